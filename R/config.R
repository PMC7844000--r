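#' Pipeline configuration
#'
#' Collects every tunable threshold of the workflow in one list so defaults can
#' be overridden without touching code. Values not supplied keep their
#' defaults, which reproduce the published decision rules.
#'
#' @param cc50_ratio observed/expected cell-number ratio at or below which a
#'   well is flagged cytotoxic. Default `0.5` (the boundary is inclusive).
#' @param jump_factor minimum fold jump in micronuclei per well between
#'   adjacent concentrations for a well to be flagged as containing
#'   precipitated compound. Default `10`.
#' @param mn_floor absolute minimum micronuclei per well for a precipitation
#'   flag; jumps below this count are never masked. Default `1000`.
#' @param positive_fold micronucleus fold change at or above which a compound
#'   is called genotoxic positive. Default `3`.
#' @param borderline_fold fold change at or above which (but below
#'   `positive_fold`) a compound is called borderline. Default `2`.
#' @param genotox_metric which per-well micronucleus statistic feeds the fold
#'   change: `"mn_per_cell"` (mean micronuclei per cell, default) or
#'   `"mn_cell_fraction"` (proportion of micronucleated cells).
#' @param sd_scale multiplier applied to the control-well sample standard
#'   deviation before it becomes the scoring Gaussian's sigma. Default `3`.
#' @param mixed_threshold if both the aneugen and clastogen scores reach this
#'   value the mechanism call is "mixed". Default `0.5`.
#' @param peak_ratio fixed ratio of the G2 (4N) to G1 (2N) Hoechst peak
#'   position. Default `2`.
#' @param band_width_sd half-width, in noise standard deviations, of the G1
#'   and G2 classification bands. Default `2`.
#' @param n_bins histogram bins for the binned likelihood used when fitting
#'   the cell-cycle model. Default `256`.
#' @param optim_maxit,optim_reltol Nelder-Mead iteration cap and relative
#'   convergence tolerance.
#'
#' @return A named list of class `ivm_config`.
#' @examples
#' cfg <- ivm_config(mixed_threshold = 0.6)
#' cfg$positive_fold
#' @export
ivm_config <- function(cc50_ratio = 0.5,
                       jump_factor = 10,
                       mn_floor = 1000,
                       positive_fold = 3,
                       borderline_fold = 2,
                       genotox_metric = c("mn_per_cell", "mn_cell_fraction"),
                       sd_scale = 3,
                       mixed_threshold = 0.5,
                       peak_ratio = 2,
                       band_width_sd = 2,
                       n_bins = 256,
                       optim_maxit = 2000,
                       optim_reltol = 1e-10) {
  genotox_metric <- match.arg(genotox_metric)
  stopifnot(cc50_ratio > 0, jump_factor > 1, mn_floor >= 0,
            positive_fold > borderline_fold, borderline_fold > 0,
            sd_scale > 0, mixed_threshold > 0, mixed_threshold <= 1,
            peak_ratio > 1, band_width_sd > 0, n_bins >= 16)
  structure(list(
    cc50_ratio = cc50_ratio,
    jump_factor = jump_factor,
    mn_floor = mn_floor,
    positive_fold = positive_fold,
    borderline_fold = borderline_fold,
    genotox_metric = genotox_metric,
    sd_scale = sd_scale,
    mixed_threshold = mixed_threshold,
    peak_ratio = peak_ratio,
    band_width_sd = band_width_sd,
    n_bins = n_bins,
    optim_maxit = optim_maxit,
    optim_reltol = optim_reltol
  ), class = "ivm_config")
}

#' @export
print.ivm_config <- function(x, ...) {
  cat("IVM pipeline configuration\n")
  for (k in names(x)) cat(sprintf("  %-16s %s\n", k, format(x[[k]])))
  invisible(x)
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
# All generator determinism flows through this helper.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
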