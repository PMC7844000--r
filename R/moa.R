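#' Fit a plate-control scoring Gaussian
#'
#' One univariate Gaussian per hallmark feature and plate: mean and sample
#' standard deviation (n-1 denominator) of the control wells' hallmark
#' values, with the SD widened by `sd_scale` (default 3). The F1 hallmark
#' (kinetochore-positive micronuclei per cell) is anchored on the plate's
#' aneugen-control wells, F2 (gamma-H2AX foci per nucleus) on the
#' clastogen-control wells.
#'
#' @param values numeric vector of control-well hallmark values (>= 2 finite
#'   values with non-zero spread).
#' @param hallmark `"F1_kt_mn"` or `"F2_h2ax_foci"`.
#' @param plate_id plate identifier carried on the fit.
#' @param sd_scale SD widening factor.
#' @return object of class `control_gaussian` with fields `mu`,
#'   `sigma_scaled`, `n_controls`, `hallmark`, `plate_id`.
#' @export
fit_control_gaussian <- function(values, hallmark = c("F1_kt_mn", "F2_h2ax_foci"),
                                 plate_id = NA_character_, sd_scale = 3) {
  hallmark <- match.arg(hallmark)
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    stop("need at least 2 finite control values to fit a scoring Gaussian",
         call. = FALSE)
  }
  s <- stats::sd(values)
  if (s == 0) {
    stop("control values have zero spread; jitter the inputs or supply a sigma override",
         call. = FALSE)
  }
  structure(list(plate_id = plate_id, hallmark = hallmark,
                 mu = mean(values), sigma_scaled = sd_scale * s,
                 n_controls = length(values)),
            class = "control_gaussian")
}

#' @export
print.control_gaussian <- function(x, ...) {
  cat(sprintf("Control Gaussian [%s, plate %s]: mu = %.5g, sigma (scaled) = %.5g, n = %d\n",
              x$hallmark, x$plate_id, x$mu, x$sigma_scaled, x$n_controls))
  invisible(x)
}

#' Mechanism score from a control Gaussian
#'
#' A hallmark value at or above the control mean scores 1.0 outright. Below
#' the mean, the Gaussian PDF at the value is divided by the PDF's maximum,
#' which in closed form is `exp(-(x - mu)^2 / (2 * sigma_scaled^2))`
#' (normalisation constants cancel). Scores are therefore bounded in (0, 1].
#'
#' @param x hallmark value(s).
#' @param g a `control_gaussian`.
#' @return numeric score(s) in (0, 1].
#' @export
mechanism_score <- function(x, g) {
  stopifnot(inherits(g, "control_gaussian"))
  ifelse(x >= g$mu, 1, exp(-(x - g$mu)^2 / (2 * g$sigma_scaled^2)))
}

#' Map a score pair and genotoxicity category to a mechanism label
#'
#' A compound called negative at the flagging stage is labelled negative
#' regardless of its scores. Otherwise: both scores at or above
#' `mixed_threshold` give "mixed"; else the larger score wins; an exact tie
#' below the threshold is undetermined.
#'
#' @param aneugen_score,clastogen_score scores in `[0, 1]`.
#' @param genotox_category `"positive"`, `"borderline"`, `"negative"` or
#'   `"undetermined"`.
#' @param mixed_threshold dual-score threshold for the mixed call.
#' @return one of `"aneugen"`, `"clastogen"`, `"mixed"`, `"negative"`,
#'   `"undetermined"`.
#' @export
call_label <- function(aneugen_score, clastogen_score, genotox_category,
                       mixed_threshold = 0.5) {
  if (genotox_category == "negative") return("negative")
  if (genotox_category == "undetermined" || is.na(aneugen_score) ||
      is.na(clastogen_score)) {
    return("undetermined")
  }
  if (aneugen_score >= mixed_threshold && clastogen_score >= mixed_threshold) {
    return("mixed")
  }
  if (aneugen_score == clastogen_score) return("undetermined")
  if (aneugen_score > clastogen_score) "aneugen" else "clastogen"
}

#' Score a compound's genotoxic mechanism
#'
#' Per replicate, the exemplar well's F1 value is scored against that
#' replicate plate's aneugen-control Gaussian and its F2 value against the
#' clastogen-control Gaussian; the two replicate predictions are aggregated
#' by mean, and the label assigned by [call_label()].
#'
#' @param exemplar_wells list of well-table rows (one per determined
#'   replicate).
#' @param f1_gaussians,f2_gaussians lists of `control_gaussian` objects
#'   plate-matched to `exemplar_wells`.
#' @param genotox_category compound-level genotoxicity category.
#' @param mixed_threshold see [call_label()].
#' @return list with `aneugen_score`, `clastogen_score`, `label`, and the
#'   per-replicate score matrix `replicate_scores`.
#' @export
score_compound <- function(exemplar_wells, f1_gaussians, f2_gaussians,
                           genotox_category, mixed_threshold = 0.5) {
  if (length(exemplar_wells) == 0 || length(f1_gaussians) == 0) {
    return(list(aneugen_score = NA_real_, clastogen_score = NA_real_,
                label = if (genotox_category == "negative") "negative" else
                  "undetermined",
                replicate_scores = NULL))
  }
  stopifnot(length(exemplar_wells) == length(f1_gaussians),
            length(exemplar_wells) == length(f2_gaussians))
  rs <- t(vapply(seq_along(exemplar_wells), function(i) {
    w <- exemplar_wells[[i]]
    c(aneugen = mechanism_score(w$kt_pos_mn_per_cell, f1_gaussians[[i]]),
      clastogen = mechanism_score(w$h2ax_foci_per_nucleus, f2_gaussians[[i]]))
  }, c(aneugen = 0, clastogen = 0)))
  a <- mean(rs[, "aneugen"])
  c_ <- mean(rs[, "clastogen"])
  list(aneugen_score = a, clastogen_score = c_,
       label = call_label(a, c_, genotox_category, mixed_threshold),
       replicate_scores = rs)
}
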