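#' Micronucleus fold change at the exemplar
#'
#' Ratio of the exemplar well's micronucleus statistic to the mean of the
#' plate DMSO wells. If the solvent baseline is exactly zero the function
#' returns `Inf` with a warning (any induction over a zero baseline is an
#' unbounded fold).
#'
#' @param exemplar_well one well-table row (the CC50 exemplar).
#' @param dmso_wells plate DMSO well-table rows with `cell_count > 0`.
#' @param metric `"mn_per_cell"` (default) or `"mn_cell_fraction"`.
#' @return non-negative scalar (possibly `Inf`).
#' @export
mn_fold_change <- function(exemplar_well, dmso_wells,
                           metric = c("mn_per_cell", "mn_cell_fraction")) {
  metric <- match.arg(metric)
  col <- if (metric == "mn_per_cell") "mn_per_cell" else
    "micronucleated_cell_fraction"
  usable <- dmso_wells[!is.na(dmso_wells$cell_count) &
                         dmso_wells$cell_count > 0, , drop = FALSE]
  if (nrow(usable) == 0) stop("no usable DMSO wells", call. = FALSE)
  baseline <- mean(usable[[col]])
  x <- exemplar_well[[col]]
  if (baseline == 0) {
    warning("DMSO micronucleus baseline is zero; fold change is Inf")
    return(if (x > 0) Inf else 0)
  }
  x / baseline
}

#' Classify a micronucleus fold change
#'
#' `fold >= positive_fold` is a positive genotoxic response,
#' `borderline_fold <= fold < positive_fold` borderline, below that negative.
#' The published rule leaves exactly 3.0 unassigned ("> 3-fold" positive vs
#' ">= 2 - < 3" borderline); here the boundary belongs to positive so the
#' categories partition the line.
#'
#' @param fold non-negative fold change.
#' @param positive_fold,borderline_fold category boundaries.
#' @return one of `"positive"`, `"borderline"`, `"negative"`.
#' @export
classify_genotox <- function(fold, positive_fold = 3, borderline_fold = 2) {
  stopifnot(is.numeric(fold), all(is.na(fold) | fold >= 0))
  ifelse(is.na(fold), NA_character_,
         ifelse(fold >= positive_fold, "positive",
                ifelse(fold >= borderline_fold, "borderline", "negative")))
}

#' Aggregate per-replicate genotoxicity calls to the compound level
#'
#' The compound fold change is the mean of the determined replicate folds and
#' the category is recomputed from that mean; replicates with no exemplar
#' (undetermined) are excluded, and a compound whose replicates are all
#' undetermined stays undetermined.
#'
#' @param folds numeric vector of per-replicate fold changes (`NA` =
#'   undetermined replicate).
#' @param positive_fold,borderline_fold category boundaries.
#' @return list with `fold_change` and `category` (including
#'   `"undetermined"`).
#' @export
aggregate_genotox <- function(folds, positive_fold = 3, borderline_fold = 2) {
  ok <- folds[!is.na(folds)]
  if (length(ok) == 0) {
    return(list(fold_change = NA_real_, category = "undetermined"))
  }
  fold <- mean(ok)
  list(fold_change = fold,
       category = classify_genotox(fold, positive_fold, borderline_fold))
}
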