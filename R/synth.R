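#' Concentration grid for the simulated dose response
#'
#' Fifteen geometrically spaced concentrations spanning 1 nM to 1 mM
#' (step ratio 10^(6/14)), matching the assay's 15-point series over six
#' decades.
#'
#' @return Numeric vector of 15 molar concentrations, ascending.
#' @export
dose_grid <- function() 10^seq(-9, -3, length.out = 15)

# Fixed inter-plate control treatments.
PACLITAXEL_CONC <- 2.5e-9   # aneugen control, 2.5 nM
ETOPOSIDE_CONC  <- 3.5e-7   # clastogen control, 0.35 uM

#' Describe a simulated test compound
#'
#' A `compound_profile` carries the latent "truth" a simulated compound obeys:
#' its class, cytotoxic potency (decreasing Hill curve), maximal micronucleus
#' induction, multiplicative shifts on the two mechanism hallmark features
#' (F1, kinetochore-positive micronuclei per cell; F2, gamma-H2AX foci per
#' nucleus) at genotoxic doses, and an optional precipitation onset
#' concentration above which well micronucleus counts are inflated
#' discontinuously.
#'
#' @param compound_id character identifier.
#' @param true_class one of `"negative"`, `"aneugen"`, `"clastogen"`,
#'   `"mixed"`.
#' @param cytotox_ec50 molar concentration of half-maximal cell loss; use a
#'   value above the dose range (e.g. `1`) for non-cytotoxic compounds.
#' @param cytotox_slope Hill slope of the survival curve.
#' @param mn_max_fold maximal fold induction of micronuclei per cell over the
#'   solvent baseline (>= 1; negatives must stay below 2).
#' @param f1_shift,f2_shift multiplier reached by the hallmark features F1/F2
#'   at fully genotoxic doses. Aneugens require `f1_shift > 1`,
#'   `f2_shift <= 1`; clastogens the converse.
#' @param precipitation_conc molar concentration at and above which the
#'   compound precipitates (`NA` for none).
#' @param gtox_potency ratio of the cytotoxic EC50 to the EC50 of
#'   micronucleus/hallmark induction; values > 1 make genotoxicity precede
#'   cytotoxicity so the effect is near-maximal at the CC50 exemplar.
#'
#' @return A list of class `compound_profile`.
#' @export
compound_profile <- function(compound_id, true_class,
                             cytotox_ec50, cytotox_slope = 2,
                             mn_max_fold = 1,
                             f1_shift = 1, f2_shift = 1,
                             precipitation_conc = NA_real_,
                             gtox_potency = 3) {
  true_class <- match.arg(true_class,
                          c("negative", "aneugen", "clastogen", "mixed"))
  if (!is.numeric(cytotox_ec50) || cytotox_ec50 <= 0)
    stop("cytotox_ec50 must be > 0", call. = FALSE)
  if (mn_max_fold < 1) stop("mn_max_fold must be >= 1", call. = FALSE)
  if (true_class == "negative" && mn_max_fold >= 2)
    stop("negative profiles must have mn_max_fold < 2", call. = FALSE)
  if (true_class == "aneugen" && !(f1_shift > 1 && f2_shift <= 1))
    stop("aneugen profiles need f1_shift > 1 and f2_shift <= 1", call. = FALSE)
  if (true_class == "clastogen" && !(f2_shift > 1 && f1_shift <= 1))
    stop("clastogen profiles need f2_shift > 1 and f1_shift <= 1", call. = FALSE)
  if (true_class == "mixed" && !(f1_shift > 1 && f2_shift > 1))
    stop("mixed profiles need f1_shift > 1 and f2_shift > 1", call. = FALSE)
  structure(list(compound_id = as.character(compound_id),
                 true_class = true_class,
                 cytotox_ec50 = cytotox_ec50,
                 cytotox_slope = cytotox_slope,
                 mn_max_fold = mn_max_fold,
                 f1_shift = f1_shift, f2_shift = f2_shift,
                 precipitation_conc = precipitation_conc,
                 gtox_potency = gtox_potency),
            class = "compound_profile")
}

#' Baseline (solvent-well) simulation parameters
#'
#' Defaults encode the assay's stated world: ~1500 cells per well after one
#' doubling of a 750-cell seed, a 3\% endogenous micronucleated-cell
#' frequency, and free-parameter solvent levels for the hallmark features.
#'
#' @param cell_count expected solvent-well cell count.
#' @param mn_rate endogenous micronuclei per cell.
#' @param f1 solvent-level kinetochore-positive micronuclei per cell.
#' @param f2 solvent-level gamma-H2AX foci per nucleus.
#' @param pan_h2ax solvent fraction of pan-gamma-H2AX nuclei (passthrough).
#' @param feature_sdlog lognormal noise sdlog applied to hallmark features.
#' @param nb_size negative-binomial size (overdispersion) for cell counts.
#' @param mu_g1,sigma G1 Hoechst peak position and shared noise SD of the
#'   per-cell intensity mixture.
#' @param cycle_weights mixture weights (g1, s, g2) of the Hoechst intensity
#'   model; must sum to 1.
#' @return Named list of baseline parameters.
#' @export
ivm_baseline <- function(cell_count = 1500, mn_rate = 0.03,
                         f1 = 0.01, f2 = 1.0, pan_h2ax = 0.02,
                         feature_sdlog = 0.10, nb_size = 50,
                         mu_g1 = 100, sigma = 8,
                         cycle_weights = c(g1 = 0.65, s = 0.20, g2 = 0.15)) {
  stopifnot(cell_count > 0, mn_rate > 0, f1 > 0, f2 > 0,
            abs(sum(cycle_weights) - 1) < 1e-8)
  list(cell_count = cell_count, mn_rate = mn_rate, f1 = f1, f2 = f2,
       pan_h2ax = pan_h2ax, feature_sdlog = feature_sdlog, nb_size = nb_size,
       mu_g1 = mu_g1, sigma = sigma, cycle_weights = cycle_weights)
}

#' Draw single-cell Hoechst intensities from the generative mixture
#'
#' Cells are assigned a phase (G1, S or G2) by the mixture weights; G1 cells
#' get 2N intensity `N(mu_g1, sigma)`, G2 cells 4N intensity
#' `N(peak_ratio * mu_g1, sigma)`, and S cells a uniform DNA content between
#' the peaks perturbed by the same Gaussian noise. Noise tails below/above
#' the peaks are what the classifier later reads as Sub-G1 and >4N.
#'
#' @param n number of cells.
#' @param mu_g1 G1 peak position.
#' @param sigma shared noise SD.
#' @param peak_ratio G2/G1 peak position ratio.
#' @param weights length-3 mixture weights (g1, s, g2), summing to 1.
#' @return data.frame with columns `hoechst_intensity` and `phase` (the
#'   generating phase, useful as simulation truth).
#' @export
simulate_intensities <- function(n, mu_g1 = 100, sigma = 8, peak_ratio = 2,
                                 weights = c(g1 = 0.65, s = 0.20, g2 = 0.15)) {
  stopifnot(n >= 0, mu_g1 > 0, sigma > 0, length(weights) == 3,
            all(weights >= 0), abs(sum(weights) - 1) < 1e-8)
  if (n == 0) {
    return(data.frame(hoechst_intensity = numeric(0),
                      phase = character(0), stringsAsFactors = FALSE))
  }
  mu_g2 <- peak_ratio * mu_g1
  phase <- sample(c("g1", "s", "g2"), n, replace = TRUE, prob = weights)
  x <- numeric(n)
  x[phase == "g1"] <- stats::rnorm(sum(phase == "g1"), mu_g1, sigma)
  x[phase == "s"]  <- stats::runif(sum(phase == "s"), mu_g1, mu_g2) +
    stats::rnorm(sum(phase == "s"), 0, sigma)
  x[phase == "g2"] <- stats::rnorm(sum(phase == "g2"), mu_g2, sigma)
  data.frame(hoechst_intensity = pmax(x, mu_g1 * 1e-3),
             phase = phase, stringsAsFactors = FALSE)
}

# Core well simulator shared by test-compound and control wells: effects are
# expressed as multipliers on the solvent baseline.
.sim_well <- function(baseline, surv, mn_fold, f1_mult, f2_mult,
                      precipitate = FALSE, cells_per_well = NULL) {
  mu_cells <- baseline$cell_count * surv
  cell_count <- if (mu_cells > 0) {
    stats::rnbinom(1, size = baseline$nb_size, mu = mu_cells)
  } else 0L
  rate <- baseline$mn_rate * mn_fold
  mn_count <- if (cell_count > 0) stats::rpois(1, cell_count * rate) else 0L
  frac <- if (cell_count > 0) {
    stats::rbinom(1, cell_count, 1 - exp(-rate)) / cell_count
  } else 0
  if (precipitate) {
    # discontinuous artifact: detector debris read as micronuclei
    mn_count <- max(20L * mn_count, 15000L)
  }
  sdlog <- baseline$feature_sdlog
  wr <- data.frame(
    cell_count = as.integer(cell_count),
    mn_count = as.integer(mn_count),
    mn_per_cell = if (cell_count > 0) mn_count / cell_count else 0,
    micronucleated_cell_fraction = min(frac, 1),
    kt_pos_mn_per_cell = baseline$f1 * f1_mult * stats::rlnorm(1, 0, sdlog),
    h2ax_foci_per_nucleus = baseline$f2 * f2_mult * stats::rlnorm(1, 0, sdlog),
    pan_h2ax_fraction = min(baseline$pan_h2ax * stats::rlnorm(1, 0, sdlog), 1),
    masked = FALSE,
    stringsAsFactors = FALSE
  )
  n_cells <- if (is.null(cells_per_well)) cell_count else
    min(cell_count, cells_per_well)
  cells <- simulate_intensities(n_cells, baseline$mu_g1, baseline$sigma,
                                weights = baseline$cycle_weights)
  list(well = wr, cells = cells)
}

# Hill helpers: surv decreases with dose, induction g rises toward 1.
.hill_surv <- function(conc, ec50, slope) {
  ifelse(conc <= 0, 1, 1 / (1 + (conc / ec50)^slope))
}
.hill_induction <- function(conc, ec50, slope) {
  ifelse(conc <= 0, 0, 1 / (1 + (ec50 / conc)^slope))
}

#' Simulate one well of a test compound
#'
#' Cell counts follow the compound's decreasing Hill survival curve around
#' the solvent baseline (negative-binomial noise); micronuclei per cell scale
#' from the endogenous rate toward `mn_max_fold` with a Hill induction curve
#' whose EC50 precedes the cytotoxic EC50 by `gtox_potency`; hallmark
#' features shift per `f1_shift`/`f2_shift` in proportion to the same
#' induction; at and above `precipitation_conc` the well's micronucleus count
#' is inflated discontinuously (>= 10-fold) while cell counts stay
#' continuous.
#'
#' @param profile a [compound_profile()].
#' @param concentration molar concentration (0 encodes solvent).
#' @param baseline solvent parameters from [ivm_baseline()].
#' @param seed optional integer; if supplied the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @param plate_id,well,replicate_id identifiers stamped on the record.
#' @param cells_per_well cap on emitted per-cell rows (default: all cells).
#' @return list with `well` (one-row data.frame in the well-table schema) and
#'   `cells` (per-cell Hoechst intensities).
#' @export
simulate_well <- function(profile, concentration, baseline = ivm_baseline(),
                          seed = NULL, plate_id = "PLATE01", well = "A01",
                          replicate_id = 1L, cells_per_well = NULL) {
  if (!inherits(profile, "compound_profile"))
    stop("profile must be a compound_profile", call. = FALSE)
  if (concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  with_seed(seed, {
    surv <- .hill_surv(concentration, profile$cytotox_ec50,
                       profile$cytotox_slope)
    g <- .hill_induction(concentration,
                         profile$cytotox_ec50 / profile$gtox_potency,
                         profile$cytotox_slope)
    precip <- !is.na(profile$precipitation_conc) &&
      concentration >= profile$precipitation_conc
    res <- .sim_well(baseline,
                     surv = surv,
                     mn_fold = 1 + (profile$mn_max_fold - 1) * g,
                     f1_mult = 1 + (profile$f1_shift - 1) * g,
                     f2_mult = 1 + (profile$f2_shift - 1) * g,
                     precipitate = precip,
                     cells_per_well = cells_per_well)
    ids <- data.frame(plate_id = plate_id, well = well, role = "test",
                      compound_id = profile$compound_id,
                      concentration = concentration,
                      replicate_id = as.integer(replicate_id),
                      stringsAsFactors = FALSE)
    res$well <- cbind(ids, res$well)
    if (nrow(res$cells) > 0) {
      res$cells <- cbind(data.frame(plate_id = plate_id, well = well,
                                    cell_index = seq_len(nrow(res$cells)),
                                    stringsAsFactors = FALSE),
                         res$cells["hoechst_intensity"])
    } else {
      res$cells <- data.frame(plate_id = character(0), well = character(0),
                              cell_index = integer(0),
                              hoechst_intensity = numeric(0))
    }
    res
  })
}

.well_name <- function(row, col) paste0(LETTERS[row], sprintf("%02d", col))

# Control block: fixed deterministic positions on every plate.
.control_positions <- function() {
  data.frame(
    well = c(.well_name(1:14, 1), .well_name(1:12, 2), .well_name(1:12, 24)),
    role = c(rep("dmso", 14), rep("aneugen_control", 12),
             rep("clastogen_control", 12)),
    stringsAsFactors = FALSE
  )
}

#' Lay out compounds on 384-well plates
#'
#' Each plate carries 14 DMSO solvent wells, 12 aneugen-control wells
#' (Paclitaxel 2.5 nM) and 12 clastogen-control wells (Etoposide 0.35 uM);
#' the remaining 346 positions hold test wells. Every compound's full series
#' (15 concentrations x `n_replicates`) is kept on one plate so replicate
#' scoring always has plate-matched controls.
#'
#' @param n_compounds number of test compounds.
#' @param n_replicates replicates per concentration.
#' @param seed integer seed controlling position shuffling (deterministic for
#'   a fixed value).
#' @param compound_ids optional character vector of ids (default CPD001...).
#' @return list of per-plate layout data.frames (`plate_id`, `well`, `role`,
#'   `compound_id`, `concentration`, `replicate_id`), with the dose grid
#'   attached as attribute `dose_grid`.
#' @export
make_layout <- function(n_compounds, n_replicates = 2, seed = 1,
                        compound_ids = sprintf("CPD%03d", seq_len(n_compounds))) {
  stopifnot(n_compounds >= 1, n_replicates >= 1,
            length(compound_ids) == n_compounds)
  grid <- dose_grid()
  wells_per_compound <- length(grid) * n_replicates
  ctrl <- .control_positions()
  capacity <- 16L * 24L - nrow(ctrl)
  if (wells_per_compound > capacity) {
    stop(sprintf(
      "capacity error: one compound needs %d wells but a plate offers %d test positions",
      wells_per_compound, capacity), call. = FALSE)
  }
  per_plate <- capacity %/% wells_per_compound
  n_plates <- ceiling(n_compounds / per_plate)
  all_wells <- as.vector(vapply(1:24, function(cc) .well_name(1:16, cc),
                                character(16)))
  test_positions <- setdiff(all_wells, ctrl$well)
  with_seed(seed, {
    lapply(seq_len(n_plates), function(p) {
      plate_id <- sprintf("PLATE%02d", p)
      ids <- compound_ids[seq((p - 1) * per_plate + 1,
                              min(p * per_plate, n_compounds))]
      test <- expand.grid(replicate_id = seq_len(n_replicates),
                          concentration = grid, compound_id = ids,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      test <- test[order(test$compound_id, test$replicate_id,
                         test$concentration), ]
      pos <- sample(test_positions, nrow(test))
      layout <- rbind(
        data.frame(plate_id = plate_id, well = ctrl$well, role = ctrl$role,
                   compound_id = c("DMSO", "PACLITAXEL",
                                   "ETOPOSIDE")[match(ctrl$role,
                                                      c("dmso", "aneugen_control",
                                                        "clastogen_control"))],
                   concentration = c(0, PACLITAXEL_CONC,
                                     ETOPOSIDE_CONC)[match(ctrl$role,
                                                           c("dmso", "aneugen_control",
                                                             "clastogen_control"))],
                   replicate_id = NA_integer_, stringsAsFactors = FALSE),
        data.frame(plate_id = plate_id, well = pos, role = "test",
                   compound_id = test$compound_id,
                   concentration = test$concentration,
                   replicate_id = as.integer(test$replicate_id),
                   stringsAsFactors = FALSE)
      )
      rownames(layout) <- NULL
      structure(layout, dose_grid = grid)
    })
  })
}

#' Scenario configuration for a synthetic screen
#'
#' Draws class-typical compound profiles. Strong defaults (maximal MN fold
#' 5-8, hallmark shifts 4-7x against a 10\% lognormal control noise, i.e.
#' several control SDs) make the classes recoverable by the downstream rules;
#' negatives stay below a 2-fold MN induction by construction.
#'
#' @param n_negative,n_aneugen,n_clastogen,n_mixed compounds per class.
#' @param n_replicates replicates per concentration.
#' @param cells_per_well cap on per-cell rows emitted per well (`NULL` = all).
#' @param precipitation_rate probability a compound is given a precipitation
#'   onset within the dose range. Default 0; artifacts are opt-in.
#' @param baseline solvent parameters, see [ivm_baseline()].
#' @return list of class `ivm_scenario`.
#' @export
ivm_scenario <- function(n_negative = 4, n_aneugen = 4, n_clastogen = 4,
                         n_mixed = 0, n_replicates = 2, cells_per_well = NULL,
                         precipitation_rate = 0, baseline = ivm_baseline()) {
  stopifnot(n_negative >= 0, n_aneugen >= 0, n_clastogen >= 0, n_mixed >= 0,
            n_negative + n_aneugen + n_clastogen + n_mixed >= 1,
            precipitation_rate >= 0, precipitation_rate <= 1)
  structure(list(n_negative = n_negative, n_aneugen = n_aneugen,
                 n_clastogen = n_clastogen, n_mixed = n_mixed,
                 n_replicates = n_replicates, cells_per_well = cells_per_well,
                 precipitation_rate = precipitation_rate, baseline = baseline),
            class = "ivm_scenario")
}

.draw_profile <- function(id, class, precipitation_rate) {
  precip <- if (stats::runif(1) < precipitation_rate) {
    10^stats::runif(1, -4, -3.3)
  } else NA_real_
  slope <- stats::runif(1, 1.5, 3)
  switch(class,
    negative = {
      cytotoxic <- stats::runif(1) < 0.5
      compound_profile(id, "negative",
                       cytotox_ec50 = if (cytotoxic) 10^stats::runif(1, -4.5, -3.5) else 1,
                       cytotox_slope = slope,
                       mn_max_fold = stats::runif(1, 1, 1.5),
                       precipitation_conc = precip)
    },
    aneugen = compound_profile(id, "aneugen",
                               cytotox_ec50 = 10^stats::runif(1, -5.5, -4.2),
                               cytotox_slope = slope,
                               mn_max_fold = stats::runif(1, 5, 8),
                               f1_shift = stats::runif(1, 4, 7),
                               f2_shift = stats::runif(1, 0.6, 1),
                               precipitation_conc = precip),
    clastogen = compound_profile(id, "clastogen",
                                 cytotox_ec50 = 10^stats::runif(1, -5.5, -4.2),
                                 cytotox_slope = slope,
                                 mn_max_fold = stats::runif(1, 5, 8),
                                 f1_shift = stats::runif(1, 0.6, 1),
                                 f2_shift = stats::runif(1, 4, 7),
                                 precipitation_conc = precip),
    mixed = compound_profile(id, "mixed",
                             cytotox_ec50 = 10^stats::runif(1, -5.5, -4.2),
                             cytotox_slope = slope,
                             mn_max_fold = stats::runif(1, 5, 8),
                             f1_shift = stats::runif(1, 4, 7),
                             f2_shift = stats::runif(1, 4, 7),
                             precipitation_conc = precip)
  )
}

# Control-well effect multipliers: Paclitaxel wells show elevated F1 and
# baseline F2; Etoposide wells the converse, with moderate MN induction.
.CTRL_EFFECTS <- list(
  dmso = list(surv = 1, mn_fold = 1, f1 = 1, f2 = 1),
  aneugen_control = list(surv = 0.90, mn_fold = 3.0, f1 = 4, f2 = 1),
  clastogen_control = list(surv = 0.85, mn_fold = 3.5, f1 = 0.8, f2 = 4)
)

#' Simulate a full synthetic screen
#'
#' Generates plate layouts via [make_layout()], draws one
#' [compound_profile()] per compound according to the scenario's class
#' counts, and simulates every control and test well plus its per-cell
#' Hoechst intensities. Output is deterministic for a fixed
#' (scenario, seed) pair.
#'
#' @param scenario an [ivm_scenario()].
#' @param seed integer seed.
#' @return list of class `ivm_screen_data` with elements `wells` (well
#'   table), `cells` (per-cell table), `truth` (compound_id, true_class),
#'   `profiles`, `dose_grid`, `seed`.
#' @examples
#' sc <- simulate_screen(ivm_scenario(1, 1, 1, cells_per_well = 50), seed = 1)
#' table(sc$wells$role)
#' @export
simulate_screen <- function(scenario, seed) {
  if (!inherits(scenario, "ivm_scenario"))
    stop("scenario must be an ivm_scenario", call. = FALSE)
  with_seed(seed, {
    classes <- rep(c("negative", "aneugen", "clastogen", "mixed"),
                   c(scenario$n_negative, scenario$n_aneugen,
                     scenario$n_clastogen, scenario$n_mixed))
    ids <- sprintf("CPD%03d", seq_along(classes))
    profiles <- Map(.draw_profile, ids, classes,
                    MoreArgs = list(precipitation_rate = scenario$precipitation_rate))
    names(profiles) <- ids
    layouts <- make_layout(length(ids), scenario$n_replicates, seed = NULL,
                           compound_ids = ids)
    baseline <- scenario$baseline
    wells <- vector("list", sum(vapply(layouts, nrow, 1L)))
    cells <- vector("list", length(wells))
    k <- 0L
    for (layout in layouts) {
      for (i in seq_len(nrow(layout))) {
        row <- layout[i, ]
        k <- k + 1L
        if (row$role == "test") {
          res <- simulate_well(profiles[[row$compound_id]], row$concentration,
                               baseline = baseline, seed = NULL,
                               plate_id = row$plate_id, well = row$well,
                               replicate_id = row$replicate_id,
                               cells_per_well = scenario$cells_per_well)
          ids_df <- res$well[, c("plate_id", "well", "role", "compound_id",
                                 "concentration", "replicate_id")]
          wr <- res$well
          cc <- res$cells
        } else {
          eff <- .CTRL_EFFECTS[[row$role]]
          res <- .sim_well(baseline, eff$surv, eff$mn_fold, eff$f1, eff$f2,
                           cells_per_well = scenario$cells_per_well)
          wr <- cbind(data.frame(plate_id = row$plate_id, well = row$well,
                                 role = row$role, compound_id = row$compound_id,
                                 concentration = row$concentration,
                                 replicate_id = row$replicate_id,
                                 stringsAsFactors = FALSE),
                      res$well)
          cc <- if (nrow(res$cells) > 0) {
            cbind(data.frame(plate_id = row$plate_id, well = row$well,
                             cell_index = seq_len(nrow(res$cells)),
                             stringsAsFactors = FALSE),
                  res$cells["hoechst_intensity"])
          } else NULL
        }
        wells[[k]] <- wr
        cells[[k]] <- cc
      }
    }
    out <- list(
      wells = do.call(rbind, wells),
      cells = do.call(rbind, cells[!vapply(cells, is.null, TRUE)]),
      truth = data.frame(compound_id = ids, true_class = classes,
                         stringsAsFactors = FALSE),
      profiles = profiles,
      dose_grid = dose_grid(),
      seed = seed
    )
    rownames(out$wells) <- NULL
    rownames(out$cells) <- NULL
    class(out) <- "ivm_screen_data"
    out
  })
}

#' @export
print.ivm_screen_data <- function(x, ...) {
  cat(sprintf("Synthetic IVM screen: %d wells on %d plate(s), %d compounds, %d cell records\n",
              nrow(x$wells), length(unique(x$wells$plate_id)),
              nrow(x$truth), nrow(x$cells)))
  print(table(x$truth$true_class))
  invisible(x)
}

#' Write a simulated screen to disk
#'
#' Emits `wells.csv`, `cells.csv`, `truth.csv` and a `meta.json` sidecar
#' (seed, dose grid, scenario echo) into `dir`.
#'
#' @param x an `ivm_screen_data` object.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_screen <- function(x, dir) {
  stopifnot(inherits(x, "ivm_screen_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(wells = file.path(dir, "wells.csv"),
             cells = file.path(dir, "cells.csv"),
             truth = file.path(dir, "truth.csv"),
             meta = file.path(dir, "meta.json"))
  write_well_table(x$wells, paths[["wells"]])
  utils::write.csv(x$cells, paths[["cells"]], row.names = FALSE)
  utils::write.csv(x$truth, paths[["truth"]], row.names = FALSE)
  meta <- list(seed = x$seed, dose_grid = x$dose_grid,
               n_compounds = nrow(x$truth),
               classes = as.list(table(x$truth$true_class)))
  jsonlite::write_json(meta, paths[["meta"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
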