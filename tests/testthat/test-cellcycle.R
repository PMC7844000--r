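test_that("fit recovers generating parameters from a 5000-cell mixture", {
  set.seed(101)
  d <- simulate_intensities(5000, mu_g1 = 100, sigma = 8, peak_ratio = 2,
                            weights = c(g1 = 0.6, s = 0.15, g2 = 0.25))
  fit <- fit_cellcycle(d$hoechst_intensity)
  expect_lt(abs(fit$mu_g1 - 100) / 100, 0.02)
  expect_lt(abs(fit$sigma - 8) / 8, 0.10)
  expect_s3_class(fit, "cellcycle_fit")

  # refit on identical data and init is bit-identical
  fit2 <- fit_cellcycle(d$hoechst_intensity)
  expect_identical(coef(fit), coef(fit2))
})

test_that("a pure G1 sample collapses onto a single component", {
  set.seed(11)
  x <- rnorm(3000, 100, 8)
  fit <- fit_cellcycle(x)
  expect_lt(abs(fit$mu_g1 - 100) / 100, 0.02)
  expect_gt(fit$weights["g1"], 0.9)
})

test_that("small samples warn and invalid intensities error", {
  set.seed(12)
  expect_warning(fit_cellcycle(rnorm(150, 100, 8)), "200")
  expect_error(fit_cellcycle(c(-1, 2, 3)), "positive")
})

test_that("phase bands follow the 2-SD rule with inner-class edge ties", {
  model <- list(mu_g1 = 100, sigma = 8, peak_ratio = 2, band_width_sd = 2)
  cls <- function(x) as.character(classify_cells(x, model))
  expect_equal(cls(100 - 2.5 * 8), "sub_g1")
  expect_equal(cls(100), "g1")
  expect_equal(cls(200), "g2")
  # exact band edges belong to the peak ("within") class
  expect_equal(cls(c(84, 116, 184, 216)), c("g1", "g1", "g2", "g2"))
  expect_equal(cls(c(83.999, 116.001, 183.999, 216.001)),
               c("sub_g1", "s", "s", "over_4n"))
})

test_that("classification matches a brute-force interval oracle and partitions the line", {
  oracle <- function(x, mu1, sigma, ratio, k) {
    mu2 <- ratio * mu1
    vapply(x, function(xi) {
      if (xi < mu1 - k * sigma) return("sub_g1")
      if (xi <= mu1 + k * sigma) return("g1")
      if (xi < mu2 - k * sigma) return("s")
      if (xi <= mu2 + k * sigma) return("g2")
      "over_4n"
    }, character(1))
  }
  set.seed(13)
  for (i in 1:20) {
    mu1 <- runif(1, 50, 200)
    sigma <- runif(1, 0.02, 0.2) * mu1
    ratio <- runif(1, 1.9, 2.1)
    if (ratio * mu1 - 2 * sigma <= mu1 + 2 * sigma) next
    model <- list(mu_g1 = mu1, sigma = sigma, peak_ratio = ratio,
                  band_width_sd = 2)
    xs <- c(seq(mu1 / 10, ratio * mu1 * 1.5, length.out = 200),
            mu1 + c(-2, 2) * sigma, ratio * mu1 + c(-2, 2) * sigma)
    got <- as.character(classify_cells(xs, model))
    expect_equal(got, oracle(xs, mu1, sigma, ratio, 2))
    expect_false(anyNA(got))  # every point gets exactly one phase
  }
  # overlapping bands leave the S band undefined
  bad <- list(mu_g1 = 100, sigma = 30, peak_ratio = 2, band_width_sd = 2)
  expect_error(classify_cells(150, bad), "overlap")
})

test_that("profiles are fractions that sum to one and rescale-invariant", {
  labs <- rep(c("sub_g1", "g1", "s", "g2", "over_4n"), c(10, 60, 10, 15, 5))
  pr <- cellcycle_profile(labs)
  expect_equal(unname(pr), c(0.10, 0.60, 0.10, 0.15, 0.05))
  expect_equal(sum(pr), 1)
  expect_equal(unname(cellcycle_profile(rep("g1", 7))), c(0, 1, 0, 0, 0))
  expect_error(cellcycle_profile(character(0)), "no labelled")

  # joint rescaling of intensities and model leaves the profile unchanged
  set.seed(14)
  d <- simulate_intensities(2000, 100, 8)
  m <- list(mu_g1 = 100, sigma = 8, peak_ratio = 2, band_width_sd = 2)
  m2 <- list(mu_g1 = 300, sigma = 24, peak_ratio = 2, band_width_sd = 2)
  p1 <- cellcycle_profile(classify_cells(d$hoechst_intensity, m))
  p2 <- cellcycle_profile(classify_cells(3 * d$hoechst_intensity, m2))
  expect_equal(p1, p2)
})

test_that("a G2-arrest scenario elevates the G2 fraction over control", {
  set.seed(15)
  ctrl <- simulate_intensities(3000, 100, 8,
                               weights = c(g1 = 0.65, s = 0.2, g2 = 0.15))
  noc <- simulate_intensities(3000, 100, 8,
                              weights = c(g1 = 0.3, s = 0.1, g2 = 0.6))
  fit <- fit_cellcycle(ctrl$hoechst_intensity)
  p_ctrl <- cellcycle_profile(classify_cells(ctrl$hoechst_intensity, fit))
  p_noc <- cellcycle_profile(classify_cells(noc$hoechst_intensity, fit))
  expect_gt(p_noc["g2"], p_ctrl["g2"] + 0.2)
})

test_that("model methods behave like a classed fit object", {
  set.seed(16)
  d <- simulate_intensities(2500, 100, 8)
  fit <- fit_cellcycle(d$hoechst_intensity)
  expect_named(coef(fit), c("mu_g1", "sigma", "w_g1", "w_s", "w_g2"))
  expect_output(print(fit), "cell-cycle fit")
  expect_output(print(summary(fit)), "bands")
  pr <- predict(fit, d$hoechst_intensity, type = "profile")
  expect_equal(sum(pr), 1)
  sim <- simulate(fit, nsim = 2, seed = 1, n = 100)
  expect_equal(nrow(sim), 200)
  expect_identical(sim, simulate(fit, nsim = 2, seed = 1, n = 100))
  r <- residuals(fit)
  expect_length(r, fit$n_bins)
  expect_equal(sum(r), 0, tolerance = 1e-6)
  expect_equal(as.numeric(logLik(fit)), fit$logLik)
})
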