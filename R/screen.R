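#' Screening configuration
#'
#' Default primary screen: single-dose 10 uM (10,000 nM), hit threshold
#' > 50% inhibition of TGF-beta1-induced myofibroblast formation,
#' viability filter < 50% reduction, confirmation cut IC50 < 10 uM.
#' Prevention mode doses compound together with TGF-beta1 at t = 0 and
#' reads at 48 h; reversal mode differentiates with TGF-beta1 for 24 h,
#' washes out, doses compound for a further 72 h and reads at 96 h.
#'
#' @param primary_conc_nM primary screen concentration (nM).
#' @param effect_threshold primary hit threshold (% inhibition).
#' @param viability_threshold maximum tolerated viability reduction (%).
#' @param confirm_ic50_nM confirmation IC50 cut (nM).
#' @param mode `"prevention"` or `"reversal"`.
#' @param tgf_dose stimulation dose (ng/ml).
#' @return list of class `screen_config`.
#' @export
screen_config <- function(primary_conc_nM = 10000, effect_threshold = 50,
                          viability_threshold = 50,
                          confirm_ic50_nM = 10000,
                          mode = c("prevention", "reversal"),
                          tgf_dose = 5) {
  mode <- match.arg(mode)
  stopifnot(effect_threshold > 0, effect_threshold <= 100,
            viability_threshold > 0, viability_threshold <= 100)
  schedule <- if (mode == "prevention") {
    list(compound_h = 0, tgf_h = 0, read_h = 48, impedance_read_h = 20)
  } else {
    list(tgf_h = 0, washout_h = 24, compound_h = 24, read_h = 96,
         impedance_read_h = 72)
  }
  structure(list(primary_conc_nM = primary_conc_nM,
                 effect_threshold = effect_threshold,
                 viability_threshold = viability_threshold,
                 confirm_ic50_nM = confirm_ic50_nM, mode = mode,
                 tgf_dose = tgf_dose, schedule = schedule),
            class = "screen_config")
}

#' Call primary hits from single-dose percent effects
#'
#' A compound enters the `primary` tier when its percent inhibition
#' exceeds the effect threshold AND its viability reduction stays below
#' the viability threshold.  Effective but cytotoxic compounds are
#' rejected with an explicit toxicity flag, never silently dropped.
#'
#' @param effects data.frame `compound_id`, `inhibition` (percent, control
#'   anchored).
#' @param viability data.frame `compound_id`, `viability_reduction`
#'   (percent); every screened compound needs a record.
#' @param cfg [screen_config()].
#' @return data.frame of class `screen_hits`: `compound_id`,
#'   `inhibition`, `viability_reduction`, `viability_pass`, `toxic_flag`,
#'   `tier` (`primary` / `rejected`).
#' @export
call_primary_hits <- function(effects, viability, cfg = screen_config()) {
  stopifnot(all(c("compound_id", "inhibition") %in% names(effects)),
            all(c("compound_id", "viability_reduction") %in% names(viability)))
  miss <- setdiff(effects$compound_id, viability$compound_id)
  if (length(miss)) {
    stop("missing viability record for: ", paste(head(miss, 5), collapse = ", "))
  }
  v <- setNames(viability$viability_reduction, viability$compound_id)
  out <- data.frame(
    compound_id = effects$compound_id,
    inhibition = effects$inhibition,
    viability_reduction = unname(v[effects$compound_id]),
    stringsAsFactors = FALSE
  )
  out$viability_pass <- out$viability_reduction < cfg$viability_threshold
  out$toxic_flag <- !out$viability_pass
  out$tier <- ifelse(out$inhibition > cfg$effect_threshold & out$viability_pass,
                     "primary", "rejected")
  class(out) <- c("screen_hits", "data.frame")
  out
}

#' Confirm primary hits by concentration response
#'
#' A primary hit is `confirmed` when its replicate potency summary is
#' uncensored with mean IC50 below the confirmation cut in the confirming
#' readout; otherwise it stays `primary`.
#'
#' @param hits [call_primary_hits()] table.
#' @param potency named list of [summarize_potency()] results (names =
#'   compound ids); hits without concentration-response data stay
#'   unconfirmed.
#' @param cfg [screen_config()].
#' @return The hit table with `ic50_nM`, `ic50_label` and updated `tier`
#'   (`confirmed` implies previously `primary`).
#' @export
confirm_hits <- function(hits, potency, cfg = screen_config()) {
  stopifnot(inherits(hits, "screen_hits"))
  hits$ic50_nM <- NA_real_
  hits$ic50_label <- NA_character_
  for (i in seq_len(nrow(hits))) {
    id <- hits$compound_id[i]
    if (hits$tier[i] != "primary" || is.null(potency[[id]])) next
    s <- potency[[id]]
    hits$ic50_label[i] <- s$label
    if (!s$censored_all) hits$ic50_nM[i] <- s$mean
    if (!s$censored_all && s$mean < cfg$confirm_ic50_nM) {
      hits$tier[i] <- "confirmed"
    }
  }
  hits
}

#' Simulate the single-dose primary screen of a compound library
#'
#' Per compound, one stimulated well at the primary concentration plus a
#' viability readout; control wells (TGF-beta1 and untreated) anchor the
#' percent scale.  All readouts use the well-level generator
#' ([simulate_well_fraction()]) with its default noise.
#'
#' @param registry [generate_compound_library()] registry.
#' @param cfg [screen_config()].
#' @param seed master seed.
#' @param n_control control wells per role.
#' @return list with `effects`, `viability`, `controls` (per-well control
#'   percent effects), `f_neg`, `f_pos`.
#' @export
simulate_primary_screen <- function(registry, cfg = screen_config(),
                                    seed = 1L, n_control = 32) {
  ctrl_frac <- function(role, i) {
    simulate_well_fraction(
      tgf_dose = if (role == "neg") cfg$tgf_dose else 0,
      mode = cfg$mode,
      seed = derive_seed(seed, "ctrl", role, i))
  }
  f_neg_w <- vapply(seq_len(n_control), function(i) ctrl_frac("neg", i),
                    numeric(1))
  f_pos_w <- vapply(seq_len(n_control), function(i) ctrl_frac("pos", i),
                    numeric(1))
  f_neg <- mean(f_neg_w); f_pos <- mean(f_pos_w)

  fr <- vapply(seq_len(nrow(registry)), function(i) {
    simulate_well_fraction(cfg$tgf_dose, registry[i, ], cfg$primary_conc_nM,
                           mode = cfg$mode,
                           seed = derive_seed(seed, registry$compound_id[i],
                                              "primary"))
  }, numeric(1))
  effects <- data.frame(
    compound_id = registry$compound_id,
    inhibition = percent_inhibition(fr, f_neg, f_pos),
    stringsAsFactors = FALSE
  )
  viability <- data.frame(
    compound_id = registry$compound_id,
    viability_reduction = vapply(seq_len(nrow(registry)), function(i) {
      simulate_viability_reduction(registry[i, ], cfg$primary_conc_nM,
                                   seed = derive_seed(seed,
                                                      registry$compound_id[i],
                                                      "viability"))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  controls <- data.frame(
    role = rep(c("neg_control", "pos_control"), each = n_control),
    percent_effect = c(percent_inhibition(f_neg_w, f_neg, f_pos),
                       percent_inhibition(f_pos_w, f_neg, f_pos))
  )
  list(effects = effects, viability = viability, controls = controls,
       f_neg = f_neg, f_pos = f_pos)
}

#' Simulate confirmation concentration-response series and fit potencies
#'
#' Serial dilution from the primary concentration (`dilution`-fold,
#' `n_conc` points, `n_rep` replicate series), percent inhibition per
#' well, one [fit_3pl()] per replicate series, summarized with
#' [summarize_potency()].
#'
#' @param registry compound registry.
#' @param compound_ids compounds to profile.
#' @param cfg [screen_config()].
#' @param seed master seed.
#' @param n_conc,dilution,n_rep series geometry.
#' @return Named list of [summarize_potency()] results.
#' @export
simulate_confirmation <- function(registry, compound_ids,
                                  cfg = screen_config(), seed = 1L,
                                  n_conc = 8, dilution = 3, n_rep = 2) {
  conc <- cfg$primary_conc_nM / dilution^(seq_len(n_conc) - 1)
  reg <- registry[match(compound_ids, registry$compound_id), , drop = FALSE]
  f_neg <- differentiation_fraction(cfg$tgf_dose)
  f_pos <- differentiation_fraction(0)
  out <- setNames(vector("list", length(compound_ids)), compound_ids)
  for (i in seq_along(compound_ids)) {
    fits <- vector("list", n_rep)
    for (r in seq_len(n_rep)) {
      y <- vapply(seq_along(conc), function(j) {
        fw <- simulate_well_fraction(
          cfg$tgf_dose, reg[i, ], conc[j], mode = cfg$mode,
          seed = derive_seed(seed, compound_ids[i], "conf", r, j))
        percent_inhibition(fw, f_neg, f_pos)
      }, numeric(1))
      fits[[r]] <- fit_3pl(log10(conc), y, direction_hint = "ascending")
    }
    out[[i]] <- summarize_potency(fits, cmax = cfg$primary_conc_nM)
  }
  out
}

#' Run a full simulated screen end-to-end
#'
#' Primary single-dose screen, viability filter, hit calling and
#' concentration-response confirmation of every primary hit; fully
#' reproducible from the master seed.
#'
#' @param registry compound registry (ground truth).
#' @param cfg [screen_config()].
#' @param seed master seed.
#' @param n_control control wells per role.
#' @return list with `hits` (tiered table), `potency`, `primary` (raw
#'   screen readouts), `zprime` of the control wells.
#' @export
run_screen <- function(registry, cfg = screen_config(), seed = 1L,
                       n_control = 32) {
  prim <- simulate_primary_screen(registry, cfg, seed, n_control)
  hits <- call_primary_hits(prim$effects, prim$viability, cfg)
  primary_ids <- hits$compound_id[hits$tier == "primary"]
  potency <- if (length(primary_ids)) {
    simulate_confirmation(registry, primary_ids, cfg, seed)
  } else list()
  hits <- confirm_hits(hits, potency, cfg)
  zp <- zprime(
    prim$controls$percent_effect[prim$controls$role == "pos_control"],
    prim$controls$percent_effect[prim$controls$role == "neg_control"])
  list(hits = hits, potency = potency, primary = prim, zprime = zp)
}

#' Run the reversal-mode (de-differentiation) protocol on a plate
#'
#' TGF-beta1 for 24 h, washout, compound for 72 h, readouts at 96 h.
#' Without a reverser the differentiated state persists (vehicle wells
#' score ~0% effect); reversers pull the myofibroblast fraction and the
#' alpha-SMA/COL1 ratios back toward the untreated baseline with their
#' reversal IC50.  Emits per-well percent effects, MRM quantifications
#' and the 72 h impedance readout.
#'
#' @param layout plate layout with compounds assigned
#'   ([assign_compounds()]).
#' @param registry compound registry.
#' @param cfg [screen_config()] with `mode = "reversal"`.
#' @param seed master seed.
#' @param kp [kinetic_params()] for the impedance readout (reversal traces
#'   use a nonzero relaxation depth).
#' @return data.frame: `well`, `role`, `compound_id`, `conc_nM`,
#'   `fraction`, `percent_effect`, `ratio_acta`, `ratio_col1`,
#'   `impedance_72h`.
#' @export
run_reversal_mode <- function(layout, registry, cfg = screen_config(mode = "reversal"),
                              seed = 1L,
                              kp = kinetic_params(relax_depth = 0.3)) {
  if (cfg$mode != "reversal") stop("config mode must be 'reversal'")
  times <- seq(0, 96, 0.5)
  get_cpd <- function(id) {
    if (is.na(id)) NULL else registry[registry$compound_id == id, , drop = FALSE]
  }
  rows <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    w <- layout[i, ]
    cpd <- get_cpd(w$compound_id)
    fr <- simulate_well_fraction(w$tgf_ng_ml, cpd, w$conc_nM,
                                 mode = "reversal",
                                 seed = derive_seed(seed, w$well, "frac"))
    ## reversal compounds act on the established state: express that as an
    ## equivalent inhibition for the protein and impedance generators
    eq <- if (is.null(cpd)) NULL else {
      e <- cpd
      e$true_ic50_nM <- if (!is.null(cpd$reversal_ic50_nM) &&
                            !is.na(cpd$reversal_ic50_nM))
        cpd$reversal_ic50_nM else cpd$true_ic50_nM
      e
    }
    ms <- simulate_msms_well(w$tgf_ng_ml, eq, w$conc_nM,
                             seed = derive_seed(seed, w$well, "msms"),
                             well = w$well)
    ms <- normalize_to_tubulin(ms)
    tr <- simulate_impedance_trace(w$tgf_ng_ml, eq, w$conc_nM, times, kp,
                                   seed = derive_seed(seed, w$well, "imp"),
                                   well = w$well)
    base <- simulate_impedance_trace(0, NULL, 0, times, kp,
                                     seed = derive_seed(seed, w$well, "base"))
    resp <- trace_response(preprocess_trace(tr, 0, base),
                           cfg$schedule$impedance_read_h)
    rows[[i]] <- data.frame(
      well = w$well, role = w$role, compound_id = w$compound_id,
      conc_nM = w$conc_nM, fraction = fr,
      ratio_acta = ms$ratio_acta, ratio_col1 = ms$ratio_col1,
      impedance_72h = resp, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  f_neg <- mean(out$fraction[out$role == "neg_control"])
  f_pos <- mean(out$fraction[out$role == "pos_control"])
  if (f_neg == f_pos) stop("degenerate controls")
  out$percent_effect <- percent_inhibition(out$fraction, f_neg, f_pos)
  out
}
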