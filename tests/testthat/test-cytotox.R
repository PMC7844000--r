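test_that("expected cell number is the plate DMSO mean", {
  wells <- rbind(make_well(role = "dmso", compound_id = "DMSO",
                           concentration = 0, cell_count = 1000L),
                 make_well(well = "B01", role = "dmso", compound_id = "DMSO",
                           concentration = 0, cell_count = 1200L),
                 make_well(well = "C01", role = "dmso", compound_id = "DMSO",
                           concentration = 0, cell_count = 800L))
  expect_equal(expected_cell_number(wells), 1000)
  expect_equal(expected_cell_number(wells[1, ]), 1000)
  single <- make_well(role = "dmso", compound_id = "DMSO", concentration = 0,
                      cell_count = 999L)
  expect_equal(expected_cell_number(single), 999)
  expect_error(expected_cell_number(make_well()), "DMSO")

  # 14 simulated solvent wells against an independent mean
  counts <- as.integer(round(1500 * exp(rnorm(14, 0, 0.1))))
  dmso14 <- do.call(rbind, lapply(seq_along(counts), function(i) {
    make_well(well = paste0(LETTERS[i], "01"), role = "dmso",
              compound_id = "DMSO", concentration = 0, cell_count = counts[i])
  }))
  expect_equal(expected_cell_number(dmso14), sum(counts) / 14)
})

test_that("cytotoxicity flagging is inclusive at a 0.5 observed/expected ratio", {
  dr <- make_dr(c(500L, 501L, 1000L))
  flags <- flag_cytotoxic(dr, expected = 1000)
  expect_identical(flags, c(TRUE, FALSE, FALSE))
})

test_that("smoothing removes only flanked singleton labels", {
  C <- TRUE; N <- FALSE
  expect_identical(smooth_labels(c(N, N, C, N, N, N)), rep(N, 6))
  # terminal cytotoxic run is untouched
  run <- c(rep(N, 12), C, C, C)
  expect_identical(smooth_labels(run), run)
  # alternating vector: interior singletons removed, endpoints kept
  alt <- rep(c(C, N), length.out = 15)
  sm <- smooth_labels(alt)
  expect_identical(sm, c(C, rep(N, 13), C))
})

test_that("smoothing matches a brute-force oracle, is idempotent, never adds labels", {
  brute <- function(v) {
    out <- v
    for (i in seq_along(v)) {
      if (i > 1 && i < length(v) && v[i] && !v[i - 1] && !v[i + 1]) {
        out[i] <- FALSE
      }
    }
    out
  }
  set.seed(42)
  for (k in 1:200) {
    v <- runif(15) < 0.4
    s <- smooth_labels(v)
    expect_identical(s, brute(v))
    expect_identical(smooth_labels(s), s)
    expect_lte(sum(s), sum(v))
  }
})

test_that("exemplar selection follows the first-cytotoxic / highest / mask rules", {
  # colchicine-like: first cytotoxic label at 1e-7 M -> exemplar 0.1 uM
  ladder <- 10^seq(-10.5, -3.5, by = 0.5)  # half-log, includes 1e-7
  dr <- make_dr(ifelse(ladder >= 1e-7, 600L, 1500L))
  dr$concentration <- ladder
  labels <- smooth_labels(flag_cytotoxic(dr, 1500))
  ex <- select_exemplar(dr, labels)
  expect_equal(ex$concentration, 1e-7)
  expect_equal(ex$provenance, "first_cytotoxic")

  # sucrose-like: no cytotoxicity -> 1 mM
  dr2 <- make_dr(rep(1500L, 15))
  ex2 <- select_exemplar(dr2, flag_cytotoxic(dr2, 1500))
  expect_equal(ex2$concentration, 1e-3)
  expect_equal(ex2$provenance, "highest_concentration")

  # mask at index 10 -> exemplar is index 9, regardless of labels
  ex3 <- select_exemplar(dr, labels, masked = dr$concentration[10])
  expect_equal(ex3$well_index, 9)
  expect_equal(ex3$provenance, "highest_after_mask")

  # masking everything -> undetermined
  ex4 <- select_exemplar(dr, labels, masked = dr$concentration[1])
  expect_equal(ex4$provenance, "undetermined")
  expect_true(is.na(ex4$concentration))
})

test_that("exemplar concentration is monotone non-increasing in added masking", {
  set.seed(7)
  for (k in 1:50) {
    dr <- make_dr(as.integer(sample(400:1600, 15, replace = TRUE)))
    labels <- smooth_labels(flag_cytotoxic(dr, 1500))
    masked <- sort(sample(dr$concentration, sample(1:4, 1)))
    ex_a <- select_exemplar(dr, labels, masked)
    more <- sort(union(masked, sample(dr$concentration, 1)))
    ex_b <- select_exemplar(dr, labels, more)
    if (!is.na(ex_a$concentration) && !is.na(ex_b$concentration)) {
      expect_lte(ex_b$concentration, ex_a$concentration)
    }
  }
})

test_that("precipitation detection flags discontinuous micronucleus jumps", {
  # the published anecdote: 50 -> 15,000 MN/well between adjacent doses
  dr <- make_dr(rep(1500L, 5), mn_counts = c(40L, 45L, 50L, 15000L, 16000L))
  masked <- detect_precipitation(dr)
  expect_equal(masked, dr$concentration[4])

  # smooth 3-fold genotoxic rise: nothing masked
  rise <- as.integer(round(45 * 3^(seq(0, 1, length.out = 15))))
  dr2 <- make_dr(rep(1500L, 15), mn_counts = rise)
  expect_length(detect_precipitation(dr2), 0)

  # boundaries are inclusive: exactly 10x jump, exactly at the floor
  dr3 <- make_dr(rep(1500L, 3), mn_counts = c(50L, 100L, 1000L))
  expect_equal(detect_precipitation(dr3), dr3$concentration[3])
  # same jump below the floor is not masked
  dr4 <- make_dr(rep(1500L, 3), mn_counts = c(5L, 10L, 100L))
  expect_length(detect_precipitation(dr4), 0)
})
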