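#' @title Well-table and cell-table I/O
#' @description Readers/writers and validators for the CSV dialects the
#'   pipeline consumes: a per-well feature table (one row per well, aggregated
#'   image-analysis features annotated with compound information) and a
#'   per-cell table of integrated nuclear Hoechst intensities.
#' @name plate_io
NULL

.WELL_COLUMNS <- c("plate_id", "well", "role", "compound_id", "concentration",
                   "replicate_id", "cell_count", "mn_count", "mn_per_cell",
                   "micronucleated_cell_fraction", "kt_pos_mn_per_cell",
                   "h2ax_foci_per_nucleus", "pan_h2ax_fraction", "masked")
.WELL_NUMERIC <- c("concentration", "cell_count", "mn_count", "mn_per_cell",
                   "micronucleated_cell_fraction", "kt_pos_mn_per_cell",
                   "h2ax_foci_per_nucleus", "pan_h2ax_fraction")
.ROLES <- c("dmso", "aneugen_control", "clastogen_control", "test")

#' Validate a well table
#'
#' Checks the schema: mandatory columns, valid 384-well positions (rows A-P,
#' columns 1-24), known roles, non-negative counts, fractions in `[0, 1]`, and
#' the consistency `mn_per_cell == mn_count / cell_count` for wells with
#' cells (wells with `cell_count == 0` carry `mn_per_cell = 0` by
#' convention and are unusable for fold-change computation).
#'
#' @param wells data.frame in the well-table schema.
#' @return the validated data.frame, invisibly coerced to canonical types.
#' @export
validate_wells <- function(wells) {
  missing <- setdiff(.WELL_COLUMNS, names(wells))
  if (length(missing) > 0) {
    stop("well table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in .WELL_NUMERIC) {
    v <- wells[[col]]
    if (is.character(v) || is.factor(v)) {
      conv <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(conv) & !is.na(v) & as.character(v) != "" &
                     !(col == "concentration"))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric value in column '%s' at row %d", col, bad[1]),
             call. = FALSE)
      }
      wells[[col]] <- conv
    }
  }
  bad_role <- which(!wells$role %in% .ROLES)
  if (length(bad_role) > 0) {
    stop(sprintf("unknown role '%s' at row %d", wells$role[bad_role[1]],
                 bad_role[1]), call. = FALSE)
  }
  ok_well <- grepl("^[A-P](0?[1-9]|1[0-9]|2[0-4])$", wells$well)
  if (any(!ok_well)) {
    stop(sprintf("invalid 384-well position '%s' at row %d",
                 wells$well[which(!ok_well)[1]], which(!ok_well)[1]),
         call. = FALSE)
  }
  chk_range <- function(col, lo, hi = Inf) {
    v <- wells[[col]]
    bad <- which(!is.na(v) & (v < lo | v > hi))
    if (length(bad) > 0) {
      stop(sprintf("column '%s' out of range [%g, %g] at row %d (value %g)",
                   col, lo, hi, bad[1], v[bad[1]]), call. = FALSE)
    }
  }
  chk_range("cell_count", 0)
  chk_range("mn_count", 0)
  chk_range("mn_per_cell", 0)
  chk_range("micronucleated_cell_fraction", 0, 1)
  chk_range("kt_pos_mn_per_cell", 0)
  chk_range("h2ax_foci_per_nucleus", 0)
  chk_range("pan_h2ax_fraction", 0, 1)
  is_test <- wells$role == "test"
  if (any(is_test & (is.na(wells$compound_id) | wells$compound_id == ""))) {
    stop("test wells must carry a compound_id", call. = FALSE)
  }
  if (any(is_test & (is.na(wells$concentration) | wells$concentration <= 0))) {
    stop("test wells must carry a strictly positive concentration",
         call. = FALSE)
  }
  has_cells <- !is.na(wells$cell_count) & wells$cell_count > 0
  mpc <- wells$mn_count[has_cells] / wells$cell_count[has_cells]
  if (any(abs(mpc - wells$mn_per_cell[has_cells]) > 1e-6 * pmax(1, mpc))) {
    stop("mn_per_cell inconsistent with mn_count / cell_count", call. = FALSE)
  }
  wells$masked <- as.logical(wells$masked)
  wells$replicate_id <- suppressWarnings(as.integer(wells$replicate_id))
  invisible(wells)
}

#' Read a well table CSV
#'
#' @param path CSV file with the documented header (comma-separated, "."
#'   decimal, UTF-8). Unknown columns are retained as passthrough.
#' @return validated well-table data.frame, input row order preserved.
#' @export
read_well_table <- function(path) {
  wells <- utils::read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  validate_wells(wells)
  wells$masked <- as.logical(wells$masked)
  wells$replicate_id <- suppressWarnings(as.integer(wells$replicate_id))
  wells
}

#' Write a well table CSV
#'
#' @param wells well-table data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_well_table <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a per-cell Hoechst intensity table CSV
#'
#' @param path CSV with columns `plate_id`, `well`, `cell_index`,
#'   `hoechst_intensity` (positive reals).
#' @return validated data.frame.
#' @export
read_cell_table <- function(path) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well", "cell_index", "hoechst_intensity")
  missing <- setdiff(need, names(cells))
  if (length(missing) > 0) {
    stop("cell table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(cells$hoechst_intensity) |
                 cells$hoechst_intensity <= 0)
  if (length(bad) > 0) {
    stop(sprintf("non-positive hoechst_intensity at row %d", bad[1]),
         call. = FALSE)
  }
  cells
}

#' Group test wells into dose-response series
#'
#' Partitions the test wells by (compound_id, replicate_id) and sorts each
#' series by strictly ascending concentration. Control and solvent wells are
#' not part of any series.
#'
#' @param wells validated well-table data.frame.
#' @return named list of data.frames (one per compound x replicate), each with
#'   attributes `compound_id` and `replicate_id`; names are
#'   `"<compound>:<replicate>"`. Empty input gives an empty list.
#' @export
group_dose_responses <- function(wells) {
  test <- wells[wells$role == "test", , drop = FALSE]
  if (nrow(test) == 0) return(structure(list(), names = character(0)))
  key <- paste(test$compound_id, test$replicate_id, sep = ":")
  out <- lapply(split(seq_len(nrow(test)), key), function(idx) {
    dr <- test[idx, , drop = FALSE]
    dr <- dr[order(dr$concentration), , drop = FALSE]
    if (anyDuplicated(dr$concentration) > 0) {
      stop(sprintf("duplicate concentration for compound %s replicate %s",
                   dr$compound_id[1], dr$replicate_id[1]), call. = FALSE)
    }
    rownames(dr) <- NULL
    attr(dr, "compound_id") <- dr$compound_id[1]
    attr(dr, "replicate_id") <- dr$replicate_id[1]
    dr
  })
  out[order(names(out))]
}

#' Write the per-compound report
#'
#' Emits a per-compound CSV (exemplar concentration(s), micronucleus fold
#' change, genotoxicity call, aneugen/clastogen scores, mechanism call,
#' cell-cycle fractions at the exemplar) and a JSON summary carrying the
#' configuration echo and call tallies. Numeric values are serialised at 6
#' significant digits. Replicates may select different exemplar
#' concentrations, so the `exemplar_concentration` column joins the
#' per-replicate values with ";".
#'
#' @param results an `ivm_screen_result` from [run_screen()].
#' @param path output CSV path; the JSON summary is written next to it with
#'   extension `.json`.
#' @return invisibly, a character vector of the two paths.
#' @export
write_report <- function(results, path) {
  stopifnot(inherits(results, "ivm_screen_result"))
  df <- results$results
  fmt <- function(x) ifelse(is.na(x), "", formatC(signif(x, 6), format = "g",
                                                  digits = 6))
  out <- data.frame(
    compound_id = df$compound_id,
    exemplar_concentration = vapply(results$replicates, function(r) {
      paste(fmt(r$exemplar_concentration), collapse = ";")
    }, character(1))[df$compound_id],
    mn_fold_change = fmt(df$mn_fold_change),
    genotox_call = df$genotox_call,
    aneugen_score = fmt(df$aneugen_score),
    clastogen_score = fmt(df$clastogen_score),
    mechanism_call = df$mechanism_call,
    cc_sub_g1 = fmt(df$cc_sub_g1), cc_g1 = fmt(df$cc_g1), cc_s = fmt(df$cc_s),
    cc_g2 = fmt(df$cc_g2), cc_over_4n = fmt(df$cc_over_4n),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  json_path <- sub("\\.csv$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  summary <- list(
    n_compounds = nrow(df),
    calls = as.list(table(df$genotox_call)),
    mechanism = as.list(table(df$mechanism_call)),
    config = unclass(results$config)
  )
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = 6,
                       pretty = TRUE)
  invisible(c(csv = path, json = json_path))
}
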