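## Independent oracles used by the tests.  They deliberately avoid the
## package's own code paths: residue masses are rebuilt from elemental
## compositions, morphology from direct min/max filters, ranks by explicit
## sorting.

## --- residue masses from elemental composition -------------------------
.ORACLE_ELEMENTS <- c(C = 12, H = 1.00782503, N = 14.00307401,
                      O = 15.99491462, S = 31.97207069)

.ORACLE_FORMULAS <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

oracle_residue_mass <- function(aa) {
  f <- .ORACLE_FORMULAS[[aa]]
  sum(.ORACLE_ELEMENTS[names(f)] * f)
}

oracle_peptide_mz <- function(seq, z) {
  res <- strsplit(seq, "")[[1]]
  M <- sum(vapply(res, oracle_residue_mass, numeric(1))) +
    2 * .ORACLE_ELEMENTS["H"] + .ORACLE_ELEMENTS["O"]
  unname((M + z * 1.00727646) / z)
}

oracle_y_mz <- function(seq, n, z = 1) {
  res <- strsplit(seq, "")[[1]]
  L <- length(res)
  M <- sum(vapply(res[(L - n + 1):L], oracle_residue_mass, numeric(1))) +
    2 * .ORACLE_ELEMENTS["H"] + .ORACLE_ELEMENTS["O"]
  unname((M + z * 1.00727646) / z)
}

oracle_b_mz <- function(seq, n, z = 1) {
  res <- strsplit(seq, "")[[1]]
  M <- sum(vapply(res[1:n], oracle_residue_mass, numeric(1)))
  unname((M + z * 1.00727646) / z)
}

## --- brute-force grayscale morphology ---------------------------------
.disc_offsets <- function(r) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= r^2 + r^2 / 4, ]  # matches a filled digital disc
}

oracle_erode <- function(m, off) {
  H <- nrow(m); W <- ncol(m)
  out <- m
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ys <- i + off$dy; xs <- j + off$dx
    keep <- ys >= 1 & ys <= H & xs >= 1 & xs <= W
    out[i, j] <- min(m[cbind(ys[keep], xs[keep])])
  }
  out
}

oracle_dilate <- function(m, off) {
  H <- nrow(m); W <- ncol(m)
  out <- m
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ys <- i + off$dy; xs <- j + off$dx
    keep <- ys >= 1 & ys <= H & xs >= 1 & xs <= W
    out[i, j] <- max(m[cbind(ys[keep], xs[keep])])
  }
  out
}

## granularity by direct opening series (independent min/max filters)
oracle_granularity <- function(m, scales) {
  total <- sum(m)
  prev <- m
  out <- numeric(length(scales))
  for (i in seq_along(scales)) {
    off <- .disc_offsets(scales[i])
    op <- pmin(oracle_dilate(oracle_erode(m, off), off), prev)
    out[i] <- 100 * sum(prev - op) / total
    prev <- op
  }
  out
}

## --- explicit average ranks + Pearson formula --------------------------
oracle_avg_ranks <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1]] == x[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

oracle_rank_pearson <- function(x, y) {
  rx <- oracle_avg_ranks(x); ry <- oracle_avg_ranks(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  if (den == 0) return(NA_real_)
  num / den
}

## --- dense grid search for the three-parameter logistic ----------------
oracle_3pl_grid <- function(x, y, logec50_grid, b_grid, t_grid) {
  best <- list(rss = Inf)
  for (b in b_grid) for (tt in t_grid) for (l in logec50_grid) {
    r <- sum((y - (b + (tt - b) / (1 + 10^(l - x))))^2)
    if (r < best$rss) best <- list(rss = r, bottom = b, top = tt, logec50 = l)
  }
  best
}
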