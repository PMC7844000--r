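test_that("dose grid has 15 points spanning 1 nM to 1 mM at a constant ratio", {
  g <- dose_grid()
  expect_length(g, 15)
  expect_equal(g[1], 1e-9)
  expect_equal(g[15], 1e-3)
  expect_equal(diff(log10(g)), rep(6 / 14, 14), tolerance = 1e-12)
})

test_that("make_layout places the published control block and all test series", {
  lay <- make_layout(1, n_replicates = 2, seed = 7)
  expect_length(lay, 1)
  p <- lay[[1]]
  expect_equal(sum(p$role == "dmso"), 14)
  expect_equal(sum(p$role == "aneugen_control"), 12)
  expect_equal(sum(p$role == "clastogen_control"), 12)
  expect_equal(sum(p$role == "test"), 30)
  expect_identical(lay, make_layout(1, n_replicates = 2, seed = 7))

  # 12 compounds x 2 replicates: 360 test wells across plates, full control
  # block on every plate, every compound complete (exhaustive bookkeeping)
  lay12 <- make_layout(12, n_replicates = 2, seed = 3)
  all <- do.call(rbind, lay12)
  expect_equal(sum(all$role == "test"), 360)
  for (p in lay12) {
    expect_equal(as.vector(table(p$role)[c("dmso", "aneugen_control",
                                           "clastogen_control")]),
                 c(14, 12, 12))
    expect_equal(anyDuplicated(p$well), 0)
  }
  test <- all[all$role == "test", ]
  for (cid in sprintf("CPD%03d", 1:12)) {
    sub <- test[test$compound_id == cid, ]
    expect_equal(nrow(sub), 30)
    expect_equal(length(unique(sub$plate_id)), 1)  # series kept on one plate
    for (r in 1:2) {
      expect_equal(sort(sub$concentration[sub$replicate_id == r]), dose_grid())
    }
  }
})

test_that("make_layout refuses series that exceed plate capacity", {
  expect_error(make_layout(1, n_replicates = 24, seed = 1), "capacity")
})

test_that("simulate_well honours class construction and baseline defaults", {
  neg <- compound_profile("neg", "negative", cytotox_ec50 = 1,
                          mn_max_fold = 1.2)
  w <- simulate_well(neg, 1e-3, seed = 11)$well
  expect_lt(w$mn_per_cell / ivm_baseline()$mn_rate, 2)
  # endogenous micronucleated-cell fraction defaults to 3%
  expect_equal(ivm_baseline()$mn_rate, 0.03)
  solv <- simulate_well(neg, 0, seed = 12)$well
  expect_equal(solv$mn_per_cell, solv$mn_count / solv$cell_count)
})

test_that("precipitation inflates micronuclei >= 10-fold while cells stay continuous", {
  prof <- compound_profile("p", "negative", cytotox_ec50 = 1, mn_max_fold = 1,
                           precipitation_conc = 1e-4)
  below <- simulate_well(prof, 3.16e-5, seed = 5)$well
  above <- simulate_well(prof, 1e-4, seed = 6)$well
  expect_gte(above$mn_count / below$mn_count, 10)
  expect_lt(abs(above$cell_count - below$cell_count) / below$cell_count, 0.5)
})

test_that("compound_profile enforces class invariants", {
  expect_error(compound_profile("x", "negative", 1, mn_max_fold = 2.5),
               "negative")
  expect_error(compound_profile("x", "aneugen", 1, mn_max_fold = 5,
                                f1_shift = 0.5), "aneugen")
  expect_error(compound_profile("x", "clastogen", 1, mn_max_fold = 5,
                                f2_shift = 1), "clastogen")
  expect_error(compound_profile("x", "negative", -1), "cytotox_ec50")
})

test_that("simulate_screen is seed-deterministic, schema-valid, and class-marked", {
  sc1 <- simulate_screen(ivm_scenario(4, 4, 4, cells_per_well = 30), seed = 1)
  sc2 <- simulate_screen(ivm_scenario(4, 4, 4, cells_per_well = 30), seed = 1)
  expect_identical(sc1$wells, sc2$wells)
  expect_identical(sc1$cells, sc2$cells)
  sc3 <- simulate_screen(ivm_scenario(4, 4, 4, cells_per_well = 30), seed = 2)
  expect_false(identical(sc1$wells, sc3$wells))

  expect_equal(nrow(sc1$truth), 12)
  expect_silent(validate_wells(sc1$wells))
  w <- sc1$wells
  expect_true(all(w$cell_count >= 0 & w$cell_count == round(w$cell_count)))
  expect_true(all(w$micronucleated_cell_fraction >= 0 &
                    w$micronucleated_cell_fraction <= 1))
  expect_true(all(w$concentration[w$role == "test"] > 0))
  expect_true(all(sc1$cells$hoechst_intensity > 0))

  # control phenotypes: Paclitaxel wells carry the F1 hallmark, Etoposide F2
  f1 <- tapply(w$kt_pos_mn_per_cell, w$role, mean)
  f2 <- tapply(w$h2ax_foci_per_nucleus, w$role, mean)
  expect_gt(f1["aneugen_control"], 2 * f1["dmso"])
  expect_lt(f2["aneugen_control"], 2 * f2["dmso"])
  expect_gt(f2["clastogen_control"], 2 * f2["dmso"])
  expect_lt(f1["clastogen_control"], 2 * f1["dmso"])
})

test_that("write_screen emits readable CSVs plus a metadata sidecar", {
  sc <- simulate_screen(ivm_scenario(1, 1, 0, cells_per_well = 20), seed = 9)
  dir <- withr::local_tempdir()
  paths <- write_screen(sc, dir)
  wells <- read_well_table(paths[["wells"]])
  expect_equal(nrow(wells), nrow(sc$wells))
  cells <- read_cell_table(paths[["cells"]])
  expect_equal(nrow(cells), nrow(sc$cells))
  meta <- jsonlite::read_json(paths[["meta"]])
  expect_equal(meta$seed, 9)
  expect_length(meta$dose_grid, 15)
})
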