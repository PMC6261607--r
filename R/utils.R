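#' Derive a reproducible child seed
#'
#' Hierarchical seeding: every stochastic stage of a simulated plate draws its
#' own seed deterministically from the plate's master seed plus a string tag
#' (typically the well id and stage name), so that wells can be regenerated
#' independently and whole plates are bit-reproducible.
#'
#' @param master integer master seed.
#' @param ... character or numeric tags identifying the stage (concatenated).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(1L, "B03", "field")
#' @export
derive_seed <- function(master, ...) {
  tag <- paste(c(master, ...), collapse = "/")
  h <- 0
  for (k in utf8ToInt(tag)) {
    ## 31-bit polynomial rolling hash; doubles stay exact below 2^53
    h <- (h * 131 + k) %% 2147483629
  }
  as.integer(h %% 2147483646L + 1)
}

#' Hill activation function
#'
#' Fractional occupancy/response `dose^h / (dose^h + ec50^h)`; 0 at dose 0,
#' 0.5 at `dose == ec50`, saturating at 1.
#'
#' @param dose non-negative dose (any concentration unit, matching `ec50`).
#' @param ec50 half-maximal dose.
#' @param h Hill slope (default 1).
#' @return Response fraction in `[0, 1)`.
#' @export
hill <- function(dose, ec50, h = 1) {
  ifelse(dose <= 0, 0, dose^h / (dose^h + ec50^h))
}

#' Fractional compound inhibition at a concentration
#'
#' Unit-slope logistic occupancy scaled by compound efficacy:
#' `efficacy * conc / (conc + ic50)`.  At `conc == ic50` a fully efficacious
#' compound inhibits exactly half of the signal, which is the midpoint
#' property the three-parameter logistic fitter recovers.
#'
#' @param conc concentration (nM).
#' @param ic50 half-maximal inhibitory concentration (nM); `Inf` or `NA`
#'   means inactive.
#' @param efficacy maximal inhibited fraction in `[0, 1]`.
#' @return Inhibited fraction of the dose-driven signal, in `[0, 1]`.
#' @export
compound_inhibition <- function(conc, ic50, efficacy = 1) {
  if (is.null(ic50) || is.na(ic50) || !is.finite(ic50) || conc <= 0) return(0)
  efficacy * conc / (conc + ic50)
}

## clamp helper
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## run code under a local RNG seed without disturbing the caller's stream
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
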