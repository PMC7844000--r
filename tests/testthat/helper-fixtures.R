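# In-code fixtures: no files, everything built at test time.

# One well-table row with sane defaults; override any field by name.
make_well <- function(plate_id = "PLATE01", well = "A01", role = "test",
                      compound_id = "CPD001", concentration = 1e-6,
                      replicate_id = 1L, cell_count = 1500L, mn_count = 45L,
                      kt_pos_mn_per_cell = 0.01, h2ax_foci_per_nucleus = 1.0,
                      pan_h2ax_fraction = 0.02, masked = FALSE,
                      micronucleated_cell_fraction = NULL) {
  mpc <- if (cell_count > 0) mn_count / cell_count else 0
  if (is.null(micronucleated_cell_fraction)) {
    micronucleated_cell_fraction <- min(mpc, 1)
  }
  data.frame(plate_id = plate_id, well = well, role = role,
             compound_id = compound_id, concentration = concentration,
             replicate_id = replicate_id, cell_count = cell_count,
             mn_count = mn_count, mn_per_cell = mpc,
             micronucleated_cell_fraction = micronucleated_cell_fraction,
             kt_pos_mn_per_cell = kt_pos_mn_per_cell,
             h2ax_foci_per_nucleus = h2ax_foci_per_nucleus,
             pan_h2ax_fraction = pan_h2ax_fraction, masked = masked,
             stringsAsFactors = FALSE)
}

# A dose-response data.frame over the standard grid with given cell/MN counts.
make_dr <- function(cell_counts, mn_counts = rep(45L, length(cell_counts)),
                    compound_id = "CPD001", replicate_id = 1L,
                    plate_id = "PLATE01", ...) {
  grid <- dose_grid()[seq_along(cell_counts)]
  do.call(rbind, lapply(seq_along(grid), function(i) {
    make_well(plate_id = plate_id, well = paste0("A", sprintf("%02d", i + 2)),
              compound_id = compound_id, concentration = grid[i],
              replicate_id = replicate_id, cell_count = cell_counts[i],
              mn_count = mn_counts[i], ...)
  }))
}

# Control block (14 dmso + 12 aneugen + 12 clastogen wells) for one plate.
make_controls <- function(plate_id = "PLATE01", dmso_cells = 1500L,
                          dmso_mn = 45L, f1_ctrl = NULL, f2_ctrl = NULL,
                          seed = 1) {
  set.seed(seed)
  if (is.null(f1_ctrl)) f1_ctrl <- 0.04 * exp(rnorm(12, 0, 0.1))
  if (is.null(f2_ctrl)) f2_ctrl <- 4.0 * exp(rnorm(12, 0, 0.1))
  rbind(
    do.call(rbind, lapply(1:14, function(i) {
      make_well(plate_id, paste0(LETTERS[i], "01"), "dmso", "DMSO", 0, NA_integer_,
                dmso_cells, dmso_mn)
    })),
    do.call(rbind, lapply(1:12, function(i) {
      make_well(plate_id, paste0(LETTERS[i], "02"), "aneugen_control",
                "PACLITAXEL", 2.5e-9, NA_integer_, 1350L, 120L,
                kt_pos_mn_per_cell = f1_ctrl[i])
    })),
    do.call(rbind, lapply(1:12, function(i) {
      make_well(plate_id, paste0(LETTERS[i], "24"), "clastogen_control",
                "ETOPOSIDE", 3.5e-7, NA_integer_, 1280L, 150L,
                h2ax_foci_per_nucleus = f2_ctrl[i])
    }))
  )
}
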