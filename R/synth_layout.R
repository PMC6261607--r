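#' Standard plate design specifications
#'
#' `hca_design()` describes a 384-well (16 x 24) high-content screening
#' plate: negative controls (5 ng/ml TGF-beta1, no compound) in the two
#' left-most columns, positive controls (no TGF-beta1, no compound) in the
#' two right-most, samples (compound + 5 ng/ml TGF-beta1) elsewhere.
#' `ipqa_design()` describes a 96-well (8 x 12) impedance/MS plate with an
#' additional `baseline` column (vehicle, no TGF-beta1) used for trace
#' subtraction.
#'
#' @param tgf_dose TGF-beta1 dose for stimulated wells (ng/ml).
#' @return A list consumed by [generate_plate_layout()]: per-role column
#'   assignments plus the stimulation dose.
#' @export
hca_design <- function(tgf_dose = 5) {
  list(neg_cols = c(1, 2), pos_cols = c(23, 24), baseline_cols = integer(),
       tgf_dose = tgf_dose)
}

#' @rdname hca_design
#' @export
ipqa_design <- function(tgf_dose = 5) {
  list(neg_cols = 1, pos_cols = 12, baseline_cols = 11, tgf_dose = tgf_dose)
}

#' Generate a complete plate layout
#'
#' Builds the well grid for a screening plate from a design specification.
#' Negative-control wells carry the TGF-beta1 stimulation dose and no
#' compound; positive-control wells carry neither; sample wells are left
#' unassigned (`compound_id` NA) until compounds are plated with
#' [assign_compounds()].
#'
#' @param rows,cols plate dimensions (16 x 24 or 8 x 12 for standard
#'   layouts).
#' @param design a design list from [hca_design()] / [ipqa_design()].
#' @return data.frame of class `plate_layout`: `well`, `row`, `col`,
#'   `role` (`neg_control`, `pos_control`, `baseline`, `sample`),
#'   `compound_id`, `conc_nM`, `tgf_ng_ml`, `replicate`.
#' @examples
#' layout <- generate_plate_layout(16, 24, hca_design())
#' table(layout$role)
#' @export
generate_plate_layout <- function(rows = 16, cols = 24, design = hca_design()) {
  stopifnot(rows >= 1, cols >= 1)
  if (length(design$neg_cols) == 0L) stop("design names no neg_control wells")
  if (length(design$pos_cols) == 0L) stop("design names no pos_control wells")
  grid <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  grid <- grid[order(grid$row, grid$col), ]
  role <- rep("sample", nrow(grid))
  role[grid$col %in% design$neg_cols] <- "neg_control"
  role[grid$col %in% design$pos_cols] <- "pos_control"
  role[grid$col %in% design$baseline_cols] <- "baseline"
  tgf <- ifelse(role %in% c("neg_control", "sample"), design$tgf_dose, 0)
  out <- data.frame(
    well = sprintf("%s%02d", LETTERS[grid$row], grid$col),
    row = grid$row, col = grid$col, role = role,
    compound_id = NA_character_, conc_nM = 0, tgf_ng_ml = tgf,
    replicate = 1L, stringsAsFactors = FALSE
  )
  class(out) <- c("plate_layout", "data.frame")
  out
}

#' Plate compounds into the sample wells of a layout
#'
#' Fills sample wells row-wise with `compound_id` / `conc_nM` pairs,
#' recycling the replicate index when a compound occupies several wells.
#'
#' @param layout a [generate_plate_layout()] result.
#' @param compound_id character vector of compound ids (one entry per
#'   sample well to fill, in plate order).
#' @param conc_nM concentration(s), recycled to match.
#' @return The layout with sample wells assigned.
#' @export
assign_compounds <- function(layout, compound_id, conc_nM) {
  idx <- which(layout$role == "sample")
  if (length(compound_id) > length(idx)) {
    stop("more compounds than sample wells")
  }
  conc_nM <- rep_len(conc_nM, length(compound_id))
  take <- idx[seq_along(compound_id)]
  layout$compound_id[take] <- compound_id
  layout$conc_nM[take] <- conc_nM
  reps <- stats::ave(seq_along(compound_id), compound_id, FUN = seq_along)
  layout$replicate[take] <- as.integer(reps)
  layout
}

#' Generate a synthetic compound registry
#'
#' Ground-truth library for screen validation: a fixed fraction of true
#' actives with log-uniform potencies, the rest inactive; an independent
#' fraction is cytotoxic with its own log-uniform toxicity EC50.  Active
#' compounds also revert established myofibroblasts, with a reversal IC50
#' equal to their prevention IC50 shifted by `reversal_shift`.
#'
#' @param n library size.
#' @param frac_active fraction of true actives in `[0, 1]`
#'   (`round(n * frac_active)` actives exactly).
#' @param potency_range IC50 range (nM), log-uniform.
#' @param efficacy_range maximal-inhibition fraction range for actives.
#' @param frac_toxic fraction of cytotoxic compounds (drawn independently
#'   of activity).
#' @param tox_range toxicity EC50 range (nM), log-uniform.
#' @param reversal_shift multiplicative potency shift of the reversal IC50
#'   relative to the prevention IC50 (default 1: same potency).
#' @param seed integer seed; the registry is bit-reproducible.
#' @return data.frame of class `compound_registry`: `compound_id`,
#'   `active`, `true_ic50_nM` (NA for inactives), `efficacy`, `toxic`,
#'   `tox_ec50_nM`, `reversal_ic50_nM`.
#' @examples
#' reg <- generate_compound_library(200, frac_active = 0.1, seed = 1)
#' sum(reg$active)
#' @export
generate_compound_library <- function(n, frac_active = 0.1,
                                      potency_range = c(10, 10000),
                                      efficacy_range = c(0.85, 1),
                                      frac_toxic = 0.05,
                                      tox_range = c(2000, 50000),
                                      reversal_shift = 1,
                                      seed = 1L) {
  stopifnot(n >= 1, frac_active >= 0, frac_active <= 1)
  n_active <- round(n * frac_active)
  if (n_active > 0 &&
      (length(potency_range) != 2L || any(potency_range <= 0) ||
       potency_range[2] < potency_range[1])) {
    stop("invalid potency range for the requested actives")
  }
  .with_seed(seed, {
    active <- rep(FALSE, n)
    if (n_active > 0) active[sample.int(n, n_active)] <- TRUE
    ic50 <- rep(NA_real_, n)
    ic50[active] <- 10^runif(n_active, log10(potency_range[1]),
                             log10(potency_range[2]))
    eff <- rep(0, n)
    eff[active] <- runif(n_active, efficacy_range[1], efficacy_range[2])
    toxic <- runif(n) < frac_toxic
    tox <- rep(NA_real_, n)
    tox[toxic] <- 10^runif(sum(toxic), log10(tox_range[1]),
                           log10(tox_range[2]))
    out <- data.frame(
      compound_id = sprintf("CPD%04d", seq_len(n)),
      active = active, true_ic50_nM = ic50, efficacy = eff,
      toxic = toxic, tox_ec50_nM = tox,
      reversal_ic50_nM = ic50 * reversal_shift,
      stringsAsFactors = FALSE
    )
    class(out) <- c("compound_registry", "data.frame")
    out
  })
}

#' Write and read the plain-text artifacts of a synthetic plate
#'
#' Plate maps, registries and ground-truth tables are exchanged as CSV.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `write_plate_csv` invisibly returns `path`; `read_plate_csv`
#'   the data.frame.
#' @export
write_plate_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
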