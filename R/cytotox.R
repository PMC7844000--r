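#' Expected cell number from plate solvent wells
#'
#' The arithmetic mean of the DMSO-well cell counts on one plate: the
#' "expected" cell number every well on that plate is compared against.
#'
#' @param plate_wells well-table rows from a single plate.
#' @return positive scalar.
#' @export
expected_cell_number <- function(plate_wells) {
  dmso <- plate_wells[plate_wells$role == "dmso", , drop = FALSE]
  if (nrow(dmso) == 0) {
    stop("no DMSO wells on plate; cannot compute expected cell number",
         call. = FALSE)
  }
  mean(dmso$cell_count)
}

#' Flag cytotoxic concentrations
#'
#' A well is cytotoxic when its observed/expected cell-count ratio is at or
#' below `cc50_ratio` (default 0.5; the boundary is inclusive).
#'
#' @param dr a dose-response data.frame (ascending concentration).
#' @param expected expected cell number from [expected_cell_number()].
#' @param cc50_ratio inclusive cytotoxicity threshold on observed/expected.
#' @return logical vector, `TRUE` = cytotoxic, aligned with `dr` rows.
#' @export
flag_cytotoxic <- function(dr, expected, cc50_ratio = 0.5) {
  stopifnot(expected > 0)
  dr$cell_count / expected <= cc50_ratio
}

#' Smooth isolated cytotoxic labels
#'
#' A cytotoxic concentration surrounded by two non-cytotoxic neighbours is
#' relabelled non-cytotoxic: single-well artifacts (pipetting, washing,
#' imaging) should not set the CC50. The pass reads the *original* label
#' vector, so the result is order-independent, endpoints are never
#' relabelled, and runs of two or more cytotoxic labels are left alone.
#'
#' @param labels logical vector of cytotoxic flags, ordered by ascending
#'   concentration.
#' @return smoothed logical vector of the same length.
#' @export
smooth_labels <- function(labels) {
  n <- length(labels)
  if (n < 3) return(labels)
  out <- labels
  interior <- 2:(n - 1)
  isolated <- labels[interior] & !labels[interior - 1] & !labels[interior + 1]
  out[interior][isolated] <- FALSE
  out
}

#' Detect precipitation artifacts in a dose response
#'
#' Compound precipitate is read by the image analysis as a discontinuous
#' explosion of "micronuclei". A concentration is flagged when its
#' micronucleus count per well jumps by at least `jump_factor` over the
#' previous (next lower) concentration AND exceeds the absolute floor
#' `mn_floor`; both boundaries are inclusive. A genuine genotoxic rise is
#' smooth by comparison and is never flagged.
#'
#' @param dr dose-response data.frame sorted by ascending concentration, with
#'   `mn_count`.
#' @param jump_factor minimum fold jump between adjacent concentrations.
#' @param mn_floor absolute minimum micronuclei/well for a flag.
#' @return numeric vector of flagged (masked) concentrations; possibly empty.
#' @export
detect_precipitation <- function(dr, jump_factor = 10, mn_floor = 1000) {
  n <- nrow(dr)
  if (n < 2) return(numeric(0))
  mn <- dr$mn_count
  prev <- mn[-n]
  cur <- mn[-1]
  # zero previous count: the ratio test is vacuous, the floor decides
  jump <- ifelse(prev == 0, TRUE, cur >= jump_factor * prev)
  flagged <- which(jump & cur >= mn_floor) + 1L
  dr$concentration[flagged]
}

#' Select the CC50 exemplar concentration
#'
#' The single concentration per compound x replicate carried forward into
#' genotoxicity flagging and mechanism scoring. With no masking, the exemplar
#' is the lowest concentration labelled cytotoxic, or the highest
#' concentration when the whole series is non-cytotoxic. When any
#' concentration is masked (precipitation), that concentration and all higher
#' ones are removed and the highest remaining concentration becomes the
#' exemplar; if masking removes everything the result is undetermined.
#'
#' @param dr dose-response data.frame sorted by ascending concentration.
#' @param labels smoothed cytotoxic flags from [smooth_labels()].
#' @param masked numeric vector of masked concentrations (possibly empty).
#' @return list with `concentration` (NA if undetermined), `well_index` (row
#'   in `dr`), and `provenance` in
#'   `{"first_cytotoxic", "highest_concentration", "highest_after_mask",
#'   "undetermined"}`.
#' @export
select_exemplar <- function(dr, labels, masked = numeric(0)) {
  conc <- dr$concentration
  stopifnot(length(labels) == length(conc), !is.unsorted(conc, strictly = TRUE))
  if (length(masked) > 0) {
    cut <- min(masked)
    keep <- which(conc < cut)
    if (length(keep) == 0) {
      return(list(concentration = NA_real_, well_index = NA_integer_,
                  provenance = "undetermined"))
    }
    idx <- max(keep)
    return(list(concentration = conc[idx], well_index = idx,
                provenance = "highest_after_mask"))
  }
  if (any(labels)) {
    idx <- which(labels)[1]
    list(concentration = conc[idx], well_index = idx,
         provenance = "first_cytotoxic")
  } else {
    idx <- length(conc)
    list(concentration = conc[idx], well_index = idx,
         provenance = "highest_concentration")
  }
}
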