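## Monoisotopic residue masses (Da) for the 20 proteinogenic amino acids,
## i.e. the mass each residue contributes inside a peptide chain.
.AA_MONO <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.MASS_WATER  <- 18.0105646
.MASS_PROTON <- 1.007276
## carbamidomethylation of cysteine (iodoacetamide derivatization)
.MASS_CAM <- 57.02146

.residue_masses <- function(sequence, carbamidomethyl = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(res, names(.AA_MONO))
  if (length(bad)) {
    stop("unknown residue symbol(s): ", paste(unique(bad), collapse = ", "))
  }
  m <- .AA_MONO[res]
  if (carbamidomethyl) m[res == "C"] <- m[res == "C"] + .MASS_CAM
  unname(m)
}

#' Monoisotopic neutral mass of a peptide
#'
#' Sum of monoisotopic residue masses plus one water (the peptide's
#' N- and C-terminal H and OH).
#'
#' @param sequence peptide sequence in one-letter amino-acid code.
#' @param carbamidomethyl add +57.02146 Da per cysteine (iodoacetamide
#'   fixed modification). Default `FALSE`; the assay's three surrogate
#'   peptides contain no cysteine.
#' @return Neutral monoisotopic mass (Da).
#' @examples
#' peptide_mass("DVNAAIATIK")
#' @export
peptide_mass <- function(sequence, carbamidomethyl = FALSE) {
  sum(.residue_masses(sequence, carbamidomethyl)) + .MASS_WATER
}

#' Precursor m/z of a protonated peptide
#'
#' `(M + z * m_proton) / z` with `M` the monoisotopic neutral mass, as
#' monitored in positive-ion electrospray MRM.
#'
#' @inheritParams peptide_mass
#' @param z positive integer charge state.
#' @return Precursor m/z (Th).
#' @examples
#' peptide_mz("DVNAAIATIK", 2)  # tubulin TBA1A surrogate, doubly protonated
#' @export
peptide_mz <- function(sequence, z = 2L, carbamidomethyl = FALSE) {
  stopifnot(z >= 1)
  (peptide_mass(sequence, carbamidomethyl) + z * .MASS_PROTON) / z
}

#' Fragment-ion m/z of a peptide (b and y series)
#'
#' For a peptide of length L and fragment index n (`1 <= n < L`):
#' y_n carries the n C-terminal residues plus water, b_n the n N-terminal
#' residues; both are protonated z times.
#'
#' @inheritParams peptide_mz
#' @param series `"b"` or `"y"`.
#' @param index fragment index (number of residues retained).
#' @return Fragment m/z (Th).
#' @examples
#' fragment_mz("DVNAAIATIK", "y", 8)   # y8 of the tubulin surrogate
#' fragment_mz("GVVGLPGQR", "y", 4)    # y4 of the COL1A1 surrogate
#' @export
fragment_mz <- function(sequence, series = c("y", "b"), index, z = 1L,
                        carbamidomethyl = FALSE) {
  series <- match.arg(series)
  m <- .residue_masses(sequence, carbamidomethyl)
  L <- length(m)
  if (index < 1L || index >= L) {
    stop("fragment index must be in [1, ", L - 1L, "] for this peptide")
  }
  stopifnot(z >= 1)
  neutral <- if (series == "y") {
    sum(m[(L - index + 1L):L]) + .MASS_WATER
  } else {
    sum(m[1:index])
  }
  (neutral + z * .MASS_PROTON) / z
}

#' Assemble an MRM transition table
#'
#' One row per (peptide, fragment) pair: computed precursor and product m/z
#' (full precision plus 2-decimal table values).
#'
#' @param peptides data.frame with columns `protein`, `peptide`,
#'   `precursor_z`, `fragment` (e.g. `"y8"`), `product_z`.
#' @param carbamidomethyl fixed cysteine modification flag.
#' @return data.frame with computed `precursor_mz` / `product_mz` (rounded,
#'   2 dp) and full-precision `precursor_mz_exact` / `product_mz_exact`.
#' @examples
#' build_mrm_table(mrm_reference_peptides())
#' @export
build_mrm_table <- function(peptides, carbamidomethyl = FALSE) {
  stopifnot(is.data.frame(peptides))
  if (nrow(peptides) == 0L) {
    return(data.frame(protein = character(), peptide = character(),
                      precursor_z = integer(), fragment = character(),
                      product_z = integer(), precursor_mz = numeric(),
                      product_mz = numeric(), precursor_mz_exact = numeric(),
                      product_mz_exact = numeric()))
  }
  need <- c("protein", "peptide", "precursor_z", "fragment", "product_z")
  stopifnot(all(need %in% names(peptides)))
  pre <- mapply(peptide_mz, peptides$peptide, peptides$precursor_z,
                MoreArgs = list(carbamidomethyl = carbamidomethyl))
  series <- substr(peptides$fragment, 1, 1)
  index <- as.integer(substring(peptides$fragment, 2))
  prod <- mapply(function(s, se, i, z) fragment_mz(s, se, i, z, carbamidomethyl),
                 peptides$peptide, series, index, peptides$product_z)
  out <- data.frame(
    protein = peptides$protein, peptide = peptides$peptide,
    precursor_z = peptides$precursor_z, fragment = peptides$fragment,
    product_z = peptides$product_z,
    precursor_mz = round(pre, 2), product_mz = round(prod, 2),
    precursor_mz_exact = pre, product_mz_exact = prod,
    row.names = NULL
  )
  ## carry instrument-tuned values through when supplied, flagging rows where
  ## the tuned setting departs from the monoisotopic calculation by > 0.05 Th
  for (col in c("instrument_precursor_mz", "instrument_product_mz")) {
    if (col %in% names(peptides)) out[[col]] <- peptides[[col]]
  }
  if (all(c("instrument_precursor_mz", "instrument_product_mz") %in% names(out))) {
    out$mz_mismatch <- abs(out$instrument_precursor_mz - out$precursor_mz) > 0.05 |
      abs(out$instrument_product_mz - out$product_mz) > 0.05
  }
  out
}

#' Reference surrogate peptides of the protein quantification assay
#'
#' The three tryptic surrogate peptides quantified by MRM: GVVGLPGQR for
#' collagen I alpha 1 (COL1A1), GYSFVTTAER for alpha-smooth-muscle actin
#' (ACTA) and DVNAAIATIK for alpha-tubulin (TBA1A), each monitored as a
#' doubly protonated precursor with a singly charged y fragment.  The
#' `instrument_*` columns are the transition settings used on the
#' triple-quadrupole instrument; for two precursors and one product these
#' differ slightly from the monoisotopic calculation and
#' [build_mrm_table()] flags the discrepancy rather than reproducing it.
#'
#' @return data.frame consumable by [build_mrm_table()].
#' @export
mrm_reference_peptides <- function() {
  data.frame(
    protein = c("COL1A1", "ACTA", "TBA1A"),
    peptide = c("GVVGLPGQR", "GYSFVTTAER", "DVNAAIATIK"),
    precursor_z = c(2L, 2L, 2L),
    fragment = c("y4", "y8", "y8"),
    product_z = c(1L, 1L, 1L),
    instrument_precursor_mz = c(441.73, 565.86, 508.29),
    instrument_product_mz = c(457.3, 577.3, 801.48)
  )
}
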