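#' Evaluate the three-parameter logistic
#'
#' `Y = Bottom + (Top - Bottom) / (1 + 10^(LogEC50 - X))` with `X` in log10
#' concentration units.  Ascending when `Top > Bottom`, descending when
#' `Top < Bottom`; the curve always passes through `(LogEC50,
#' (Top + Bottom)/2)`.
#'
#' @param x log10 concentration.
#' @param bottom,top asymptotes (response units).
#' @param logec50 log10 of the half-maximal concentration.
#' @return Response values.
#' @export
logistic3 <- function(x, bottom, top, logec50) {
  bottom + (top - bottom) / (1 + 10^(logec50 - x))
}

#' Fit a three-parameter logistic concentration-response curve
#'
#' Unweighted least squares with deterministic self-starting values:
#' Bottom/Top from the dose-averaged responses at the extreme
#' concentrations, LogEC50 from the half-maximal crossing of a linear
#' interpolation of the dose means.  Solved with [minpack.lm::nlsLM()]
#' (Levenberg-Marquardt), falling back to Nelder-Mead on the residual sum
#' of squares if that fails.
#'
#' Zero-concentration anchor wells must be excluded from `x` upstream
#' (log10(0) is undefined); they define the percent scale, not the curve.
#' A fitted LogEC50 outside the tested concentration range, or a flat
#' response, yields a censored result rather than an error.
#'
#' @param x log10 concentrations, finite, spanning at least 2 log units.
#' @param y responses, same length.
#' @param direction_hint optional `"ascending"` or `"descending"`; when
#'   absent the direction is inferred from the fitted asymptotes.
#' @return An object of class `dose_response_fit`: list with `bottom`,
#'   `top`, `logec50`, `ec50` (linear scale), `direction`, `censor`
#'   (`"none"`, `"above_max"`, `"below_min"`), `rss`, `n`, `x_range`.
#' @examples
#' x <- log10(c(1, 3, 10, 30, 100, 300))
#' y <- logistic3(x, 0, 100, 1)
#' fit_3pl(x, y)$logec50
#' @export
fit_3pl <- function(x, y, direction_hint = NULL) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) stop("at least 4 finite points are required")
  if (diff(range(x)) < 2) stop("concentrations must span at least 2 log units")

  xr <- range(x)
  mk_fit <- function(bottom, top, logec50, censor, rss) {
    direction <- if (is.na(top) || is.na(bottom)) NA_character_
      else if (top >= bottom) "ascending" else "descending"
    structure(list(bottom = bottom, top = top, logec50 = logec50,
                   ec50 = 10^logec50, direction = direction, censor = censor,
                   rss = rss, n = length(x), x_range = xr),
              class = "dose_response_fit")
  }

  ## dose-averaged responses, ordered by concentration
  mu <- tapply(y, x, mean)
  xs <- as.numeric(names(mu)); mu <- as.numeric(mu)

  ## flat response: no information about a half-maximal crossing
  if (var(y) < 1e-12 || diff(range(mu)) < 1e-8 * max(1, max(abs(mu)))) {
    return(mk_fit(mu[1], mu[length(mu)], xr[2],
                  censor = "above_max", rss = sum((y - mean(y))^2)))
  }

  bottom0 <- mu[1]; top0 <- mu[length(mu)]
  if (!is.null(direction_hint)) {
    direction_hint <- match.arg(direction_hint, c("ascending", "descending"))
    if (direction_hint == "ascending" && bottom0 > top0) {
      bottom0 <- min(mu); top0 <- max(mu)
    }
    if (direction_hint == "descending" && bottom0 < top0) {
      bottom0 <- max(mu); top0 <- min(mu)
    }
  }
  half <- (bottom0 + top0) / 2
  ## first crossing of the half level along the interpolated dose means
  cross <- which(diff(sign(mu - half)) != 0)
  log0 <- if (length(cross)) {
    i <- cross[1]
    if (abs(mu[i + 1] - mu[i]) < 1e-12) xs[i]
    else xs[i] + (half - mu[i]) / (mu[i + 1] - mu[i]) * (xs[i + 1] - xs[i])
  } else mean(xr)

  fit <- tryCatch({
    m <- minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(logec50 - x)),
      start = list(bottom = bottom0, top = top0, logec50 = log0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    p <- coef(m)
    list(p = p, rss = sum(resid(m)^2))
  }, error = function(e) NULL)

  if (is.null(fit)) {
    obj <- function(p) sum((y - logistic3(x, p[1], p[2], p[3]))^2)
    o <- optim(c(bottom0, top0, log0), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
    fit <- list(p = setNames(o$par, c("bottom", "top", "logec50")),
                rss = o$value)
  }

  p <- fit$p
  censor <- if (p[["logec50"]] > xr[2]) "above_max"
    else if (p[["logec50"]] < xr[1]) "below_min" else "none"
  mk_fit(p[["bottom"]], p[["top"]], p[["logec50"]], censor, fit$rss)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<3PL fit> Bottom %.3g, Top %.3g, LogEC50 %.4g (EC50 %.4g), %s, censor: %s, n = %d\n",
    x$bottom, x$top, x$logec50, x$ec50, x$direction, x$censor, x$n))
  invisible(x)
}

#' Summarize replicate potencies with censoring
#'
#' Uncensored EC50/IC50 values are averaged on the linear concentration
#' scale (arithmetic mean +/- SD over independent experiments, SD only for
#' n >= 2).  When every replicate is censored the summary is reported as a
#' bound, `"> cmax (n = k)"`.
#'
#' @param fits list of [fit_3pl()] results (or numeric EC50 values, taken
#'   as uncensored).
#' @param cmax highest tested concentration (nM), the censoring bound.
#' @return list with `mean`, `sd`, `n`, `n_censored`, `censored_all`,
#'   `bound`, and a formatted `label` such as `"47 ± 9.9 (n = 2)"` or
#'   `"> 50,000 (n = 1)"`.
#' @export
summarize_potency <- function(fits, cmax = 50000) {
  if (length(fits) == 0L) stop("no fits to summarize")
  if (is.numeric(fits)) {
    ec50 <- fits; cens <- rep(FALSE, length(fits))
  } else {
    if (inherits(fits, "dose_response_fit")) fits <- list(fits)
    ec50 <- vapply(fits, function(f) f$ec50, numeric(1))
    cens <- vapply(fits, function(f) f$censor != "none", logical(1))
  }
  n <- length(ec50)
  if (all(cens)) {
    lab <- sprintf("> %s (n = %d)", format(cmax, big.mark = ","), n)
    return(list(mean = NA_real_, sd = NA_real_, n = n, n_censored = n,
                censored_all = TRUE, bound = cmax, label = lab))
  }
  v <- ec50[!cens]
  m <- mean(v)
  s <- if (length(v) >= 2L) sd(v) else NA_real_
  lab <- if (is.na(s)) {
    sprintf("%s (n = %d)", format(signif(m, 2), big.mark = ","), n)
  } else {
    sprintf("%s ± %s (n = %d)", format(signif(m, 2), big.mark = ","),
            format(signif(s, 2), big.mark = ","), n)
  }
  list(mean = m, sd = s, n = n, n_censored = sum(cens),
       censored_all = FALSE, bound = cmax, label = lab)
}

#' Z-prime screening-window coefficient
#'
#' `Z' = 1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|` with sample
#' standard deviations (n - 1 denominator).  Z' <= 1 always; values >= 0.5
#' indicate a robust screening window.
#'
#' @param pos_effects percent-effect values of positive-control wells
#'   (>= 2 values).
#' @param neg_effects percent-effect values of negative-control wells.
#' @return list with `mu_pos`, `sigma_pos`, `mu_neg`, `sigma_neg`,
#'   `zprime` (NA with `degenerate = TRUE` if the control means coincide).
#' @export
zprime <- function(pos_effects, neg_effects) {
  stopifnot(length(pos_effects) >= 2L, length(neg_effects) >= 2L)
  mp <- mean(pos_effects); mn <- mean(neg_effects)
  sp <- sd(pos_effects); sn <- sd(neg_effects)
  if (mp == mn) {
    return(list(mu_pos = mp, sigma_pos = sp, mu_neg = mn, sigma_neg = sn,
                zprime = NA_real_, degenerate = TRUE))
  }
  list(mu_pos = mp, sigma_pos = sp, mu_neg = mn, sigma_neg = sn,
       zprime = 1 - 3 * (sp + sn) / abs(mp - mn), degenerate = FALSE)
}

#' Percent inhibition on the control-anchored scale
#'
#' `100 * (mu_neg - sample) / (mu_neg - mu_pos)`: 0 at the TGF-treated
#' (negative) control mean, 100 at the untreated (positive) control mean.
#' Shares its semantics with [well_percent_effect()].
#'
#' @param sample_value readout value(s).
#' @param mu_neg,mu_pos control means (must differ).
#' @return Percent inhibition (not clipped).
#' @export
percent_inhibition <- function(sample_value, mu_neg, mu_pos) {
  if (mu_neg == mu_pos) stop("degenerate controls: mu_neg == mu_pos")
  100 * (mu_neg - sample_value) / (mu_neg - mu_pos)
}
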