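#' Run the three-step genotoxicity workflow
#'
#' Executes the full per-compound pipeline on a validated well table:
#' precipitation detection, plate-anchored CC50 exemplar selection
#' (expected cell number from plate DMSO wells, inclusive 50\% ratio
#' flagging, flanked-label smoothing, mask truncation — wells pre-marked
#' `masked = TRUE` in the input join the precipitation flags), micronucleus
#' fold-change flagging against the plate solvent baseline, and — for
#' positive and borderline compounds — Gaussian mechanism scoring against the
#' plate aneugen/clastogen controls with replicate aggregation by mean. When
#' a per-cell Hoechst table is supplied, a cell-cycle model is fitted to each
#' plate's DMSO cells and the exemplar wells' cells are profiled with it.
#' The pipeline is fully deterministic: all stochasticity lives in the
#' synthetic generator behind explicit seeds.
#'
#' @param wells well-table data.frame (see [read_well_table()]).
#' @param cells optional per-cell table (see [read_cell_table()]); `NULL`
#'   skips cell-cycle profiling.
#' @param config an [ivm_config()].
#' @return object of class `ivm_screen_result`: `results` (one row per
#'   compound), `replicates` (per-replicate detail), `plates` (per-plate
#'   baselines and control Gaussians), `config`.
#' @export
run_screen <- function(wells, cells = NULL, config = ivm_config()) {
  isTRUE_vec <- function(x) !is.na(x) & x
  wells <- validate_wells(wells)

  plate_ids <- unique(wells$plate_id)
  plates <- lapply(plate_ids, function(pid) {
    pw <- wells[wells$plate_id == pid, , drop = FALSE]
    for (need in c("dmso", "aneugen_control", "clastogen_control")) {
      if (sum(pw$role == need) == 0) {
        stop(sprintf("plate %s is missing required %s wells", pid, need),
             call. = FALSE)
      }
    }
    dmso <- pw[pw$role == "dmso", , drop = FALSE]
    an <- pw[pw$role == "aneugen_control", , drop = FALSE]
    cl <- pw[pw$role == "clastogen_control", , drop = FALSE]
    cc_fit <- NULL
    if (!is.null(cells)) {
      key <- paste(cells$plate_id, cells$well)
      dmso_key <- paste(pid, dmso$well)
      xs <- cells$hoechst_intensity[key %in% dmso_key]
      if (length(xs) >= 50) {
        cc_fit <- suppressWarnings(fit_cellcycle(
          xs, peak_ratio = config$peak_ratio, n_bins = config$n_bins,
          band_width_sd = config$band_width_sd, maxit = config$optim_maxit,
          reltol = config$optim_reltol))
      }
    }
    list(plate_id = pid,
         expected_cells = expected_cell_number(pw),
         dmso = dmso,
         f1_gaussian = fit_control_gaussian(an$kt_pos_mn_per_cell,
                                            "F1_kt_mn", pid,
                                            sd_scale = config$sd_scale),
         f2_gaussian = fit_control_gaussian(cl$h2ax_foci_per_nucleus,
                                            "F2_h2ax_foci", pid,
                                            sd_scale = config$sd_scale),
         cellcycle = cc_fit)
  })
  names(plates) <- plate_ids

  drs <- group_dose_responses(wells)
  metric <- config$genotox_metric

  # per-replicate stage: masking, labels, exemplar, fold
  reps <- lapply(drs, function(dr) {
    pid <- dr$plate_id[1]
    pl <- plates[[pid]]
    # input-masked wells (upstream QC) join the precipitation flags
    masked <- union(detect_precipitation(dr, config$jump_factor,
                                         config$mn_floor),
                    dr$concentration[isTRUE_vec(dr$masked)])
    labels <- smooth_labels(flag_cytotoxic(dr, pl$expected_cells,
                                           config$cc50_ratio))
    ex <- select_exemplar(dr, labels, masked)
    fold <- NA_real_
    well <- NULL
    if (!is.na(ex$well_index)) {
      well <- dr[ex$well_index, , drop = FALSE]
      if (well$cell_count > 0) {
        fold <- mn_fold_change(well, pl$dmso, metric)
      }
    }
    list(compound_id = attr(dr, "compound_id"),
         replicate_id = attr(dr, "replicate_id"),
         plate_id = pid, exemplar_concentration = ex$concentration,
         provenance = ex$provenance, n_masked = length(masked),
         fold = fold, well = well)
  })

  compound_ids <- unique(vapply(reps, `[[`, character(1), "compound_id"))
  replicates <- list()
  rows <- lapply(compound_ids, function(cid) {
    rr <- reps[vapply(reps, function(r) r$compound_id == cid, TRUE)]
    folds <- vapply(rr, `[[`, numeric(1), "fold")
    agg <- aggregate_genotox(folds, config$positive_fold,
                             config$borderline_fold)
    determined <- !vapply(rr, function(r) is.null(r$well), TRUE) & !is.na(folds)
    sc <- list(aneugen_score = NA_real_, clastogen_score = NA_real_,
               label = switch(agg$category, undetermined = "undetermined",
                              "negative"))
    if (agg$category %in% c("positive", "borderline")) {
      rr_d <- rr[determined]
      sc <- score_compound(
        lapply(rr_d, `[[`, "well"),
        lapply(rr_d, function(r) plates[[r$plate_id]]$f1_gaussian),
        lapply(rr_d, function(r) plates[[r$plate_id]]$f2_gaussian),
        agg$category, config$mixed_threshold)
    }
    cc <- rep(NA_real_, 5)
    if (!is.null(cells)) {
      profs <- list()
      for (r in rr[determined]) {
        fitp <- plates[[r$plate_id]]$cellcycle
        if (is.null(fitp) || is.null(r$well)) next
        sel <- cells$plate_id == r$plate_id & cells$well == r$well$well
        xs <- cells$hoechst_intensity[sel]
        if (length(xs) == 0) next
        profs[[length(profs) + 1]] <- cellcycle_profile(classify_cells(xs, fitp))
      }
      if (length(profs) > 0) cc <- colMeans(do.call(rbind, profs))
    }
    replicates[[cid]] <<- list(
      replicate_id = unname(vapply(rr, `[[`, integer(1), "replicate_id")),
      exemplar_concentration = unname(vapply(rr, `[[`, numeric(1),
                                             "exemplar_concentration")),
      provenance = unname(vapply(rr, `[[`, character(1), "provenance")),
      fold = unname(folds))
    data.frame(compound_id = cid, n_replicates = length(rr),
               mn_fold_change = agg$fold_change, genotox_call = agg$category,
               aneugen_score = sc$aneugen_score,
               clastogen_score = sc$clastogen_score,
               mechanism_call = sc$label,
               cc_sub_g1 = cc[1], cc_g1 = cc[2], cc_s = cc[3], cc_g2 = cc[4],
               cc_over_4n = cc[5], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(list(results = res, replicates = replicates, plates = plates,
                 config = config),
            class = "ivm_screen_result")
}

#' @export
print.ivm_screen_result <- function(x, ...) {
  cat(sprintf("IVM screen result: %d compounds on %d plate(s)\n",
              nrow(x$results), length(x$plates)))
  cat("genotoxicity calls: ")
  print(table(x$results$genotox_call))
  cat("mechanism calls:    ")
  print(table(x$results$mechanism_call))
  invisible(x)
}

#' @export
summary.ivm_screen_result <- function(object, ...) {
  print(object)
  cat("\nper-compound results:\n")
  print(object$results, digits = 4, row.names = FALSE)
  invisible(object)
}

#' Multiclass Matthews correlation coefficient
#'
#' Correlation-form generalisation over a confusion matrix `C` (rows = truth,
#' columns = predicted): with `c = trace(C)`, `s = sum(C)`, `p_k` the
#' predicted-class totals and `t_k` the true-class totals,
#' `MCC = (c*s - sum(p*t)) / sqrt((s^2 - sum(p^2)) * (s^2 - sum(t^2)))`.
#' A zero denominator (all predictions or all truths in one class) gives 0.
#'
#' @param cm square confusion matrix.
#' @return scalar in `[-1, 1]`.
#' @export
mcc_multiclass <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  s <- sum(cm)
  c_ <- sum(diag(cm))
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  denom <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (denom == 0) return(0)
  (c_ * s - sum(p_k * t_k)) / denom
}

#' Evaluate screen predictions against truth labels
#'
#' Builds the confusion matrix over the final per-compound labels (negative
#' compounds keep their flagging call; positive/borderline compounds carry
#' their mechanism label) and reports accuracy and the multiclass Matthews
#' correlation coefficient. Undetermined compounds are excluded from the
#' matrix and reported separately.
#'
#' @param result an `ivm_screen_result`.
#' @param truth data.frame with `compound_id` and `true_class`.
#' @param mixed `"own"` treats mixed as its own class; `"exclude"` drops
#'   mixed-truth compounds from the matrix.
#' @return object of class `ivm_eval` with `confusion`, `accuracy`, `mcc`,
#'   `n_undetermined`.
#' @export
evaluate_screen <- function(result, truth, mixed = c("own", "exclude")) {
  mixed <- match.arg(mixed)
  stopifnot(inherits(result, "ivm_screen_result"))
  res <- result$results
  missing_truth <- setdiff(res$compound_id, truth$compound_id)
  if (length(missing_truth) > 0) {
    stop("no truth label for compound(s): ",
         paste(missing_truth, collapse = ", "), call. = FALSE)
  }
  df <- merge(res[, c("compound_id", "mechanism_call")],
              truth[, c("compound_id", "true_class")], by = "compound_id")
  bad <- setdiff(df$true_class, c("negative", "aneugen", "clastogen", "mixed"))
  if (length(bad) > 0) {
    stop("unknown truth label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n_und <- sum(df$mechanism_call == "undetermined")
  df <- df[df$mechanism_call != "undetermined", , drop = FALSE]
  if (mixed == "exclude") {
    df <- df[df$true_class != "mixed", , drop = FALSE]
  }
  lev <- c("negative", "aneugen", "clastogen")
  if (mixed == "own" && ("mixed" %in% df$true_class ||
                         "mixed" %in% df$mechanism_call)) {
    lev <- c(lev, "mixed")
  }
  cm <- table(truth = factor(df$true_class, levels = lev),
              predicted = factor(df$mechanism_call, levels = lev))
  structure(list(confusion = cm,
                 accuracy = if (sum(cm) > 0) sum(diag(cm)) / sum(cm) else
                   NA_real_,
                 mcc = mcc_multiclass(cm),
                 n_undetermined = n_und),
            class = "ivm_eval")
}

#' @export
print.ivm_eval <- function(x, ...) {
  cat("Screen evaluation\n")
  print(x$confusion)
  cat(sprintf("accuracy = %.4f, multiclass MCC = %.4f (%d undetermined excluded)\n",
              x$accuracy, x$mcc, x$n_undetermined))
  invisible(x)
}
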