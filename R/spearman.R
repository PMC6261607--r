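## all permutations of 1..n as an (n! x n) integer matrix (n <= 9)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    idx <- seq_len(nrow(sub)) + r
    out[idx, 1] <- i
    rest <- seq_len(n)[-i]
    out[idx, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation with a two-tailed p value
#'
#' Spearman's r computed as the Pearson correlation of average-tie ranks.
#' The two-tailed p value is exact for n <= 9 (full enumeration of all n!
#' permutations of one rank vector) and uses the t approximation
#' `t = r * sqrt((n-2)/(1-r^2))` on n - 2 degrees of freedom otherwise.
#'
#' @param x,y numeric vectors of equal length (n >= 3), no NAs.
#' @param method `"auto"` (exact for n <= 9), `"permutation"` or `"t"`.
#' @return list with `r`, `p`, `n`, `method`.
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman_cor <- function(x, y, method = c("auto", "permutation", "t")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired values")
  if (anyNA(x) || anyNA(y)) stop("NA values are not allowed")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, method = "degenerate"))
  }
  r <- cor(rx, ry)
  if (method == "auto") method <- if (n <= 9L) "permutation" else "t"
  p <- if (method == "permutation") {
    if (n > 9L) stop("exact permutation p limited to n <= 9")
    P <- .permutations(n)
    rxc <- rx - mean(rx)
    ## r under each permutation of the y-ranks, via one matrix product
    num <- matrix(ry[P], nrow(P), n) %*% rxc
    rall <- as.numeric(num) / ((n - 1) * sd(rx) * sd(ry))
    mean(abs(rall) >= abs(r) - 1e-12)
  } else {
    tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-15))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = min(p, 1), n = n, method = method)
}

#' Pairwise Spearman correlation of potencies across assay readouts
#'
#' Correlates compound potencies (IC50/EC50, nM) between every pair of
#' readouts.  Censored potencies enter at their bound value and are
#' flagged; `exclude_censored = TRUE` recomputes with censored rows
#' dropped (sensitivity analysis).  Each pair needs >= 5 compounds with
#' values in both readouts.
#'
#' @param potency_table data.frame or matrix, rows = compounds, columns =
#'   readouts, entries = potency in nM (NA allowed).
#' @param censored optional logical matrix of the same shape marking
#'   bound-value (censored) entries.
#' @param exclude_censored drop censored entries instead of using bounds.
#' @param alpha significance level for the two-tailed p (default 0.05).
#' @return list with matrices `r`, `p`, `n`, `significant`, plus
#'   `n_censored_used`.
#' @export
correlate_readouts <- function(potency_table, censored = NULL,
                               exclude_censored = FALSE, alpha = 0.05) {
  m <- as.matrix(potency_table)
  storage.mode(m) <- "double"
  if (is.null(censored)) censored <- matrix(FALSE, nrow(m), ncol(m))
  if (exclude_censored) m[censored] <- NA_real_
  k <- ncol(m)
  nm <- colnames(m)
  if (is.null(nm)) nm <- paste0("readout", seq_len(k))
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) nmat[i, i] <- sum(is.finite(m[, i]))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- is.finite(m[, i]) & is.finite(m[, j])
      if (sum(ok) < 5L) stop("fewer than 5 paired potencies for ",
                             nm[i], " vs ", nm[j])
      sc <- spearman_cor(m[ok, i], m[ok, j])
      r[i, j] <- r[j, i] <- sc$r
      p[i, j] <- p[j, i] <- sc$p
      nmat[i, j] <- nmat[j, i] <- sc$n
    }
  }
  list(r = r, p = p, n = nmat, significant = p < alpha,
       n_censored_used = if (exclude_censored) 0L else sum(censored))
}
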