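test_that("primary hit calling applies the effect and viability filters", {
  cfg <- screen_config()
  eff <- data.frame(compound_id = c("A", "B", "C"),
                    inhibition = c(80, 80, 30))
  via <- data.frame(compound_id = c("A", "B", "C"),
                    viability_reduction = c(10, 60, 5))
  hits <- call_primary_hits(eff, via, cfg)
  expect_equal(hits$tier, c("primary", "rejected", "rejected"))
  expect_true(hits$toxic_flag[hits$compound_id == "B"])   # flagged, not dropped
  expect_false(hits$toxic_flag[hits$compound_id == "C"])
  expect_error(call_primary_hits(eff, via[1:2, ], cfg), "missing viability")
})

test_that("lowering the effect threshold never removes a primary hit", {
  set.seed(1)
  eff <- data.frame(compound_id = sprintf("C%02d", 1:40),
                    inhibition = runif(40, -10, 110))
  via <- data.frame(compound_id = eff$compound_id,
                    viability_reduction = runif(40, 0, 80))
  strict <- call_primary_hits(eff, via, screen_config(effect_threshold = 70))
  loose <- call_primary_hits(eff, via, screen_config(effect_threshold = 40))
  strict_ids <- strict$compound_id[strict$tier == "primary"]
  loose_ids <- loose$compound_id[loose$tier == "primary"]
  expect_true(all(strict_ids %in% loose_ids))
})

test_that("confirmation requires an uncensored IC50 below the cut", {
  cfg <- screen_config()
  eff <- data.frame(compound_id = c("A", "B"), inhibition = c(80, 75))
  via <- data.frame(compound_id = c("A", "B"), viability_reduction = c(5, 5))
  hits <- call_primary_hits(eff, via, cfg)
  pot <- list(A = summarize_potency(c(500, 520)),
              B = summarize_potency(list(structure(
                list(ec50 = 5e4, censor = "above_max"),
                class = "dose_response_fit")), cmax = 50000))
  out <- confirm_hits(hits, pot, cfg)
  expect_equal(out$tier[out$compound_id == "A"], "confirmed")
  expect_equal(out$tier[out$compound_id == "B"], "primary")
  expect_equal(out$ic50_label[out$compound_id == "B"], "> 50,000 (n = 1)")
})

test_that("a simulated 200-compound screen recovers the registry truth", {
  reg <- generate_compound_library(200, frac_active = 0.1,
                                   potency_range = c(10, 1000), seed = 5)
  res <- run_screen(reg, screen_config(), seed = 42)
  h <- res$hits
  called <- h$tier %in% c("primary", "confirmed")
  ## recall over actives the screen is designed to keep (non-cytotoxic)
  keep <- reg$active & !reg$toxic
  expect_gte(sum(called & keep) / sum(keep), 0.9)
  expect_lte(sum(called & !reg$active) / sum(!reg$active), 0.05)
  conf <- h$compound_id[h$tier == "confirmed"]
  expect_true(all(reg$active[match(conf, reg$compound_id)]))
  expect_gte(res$zprime$zprime, 0.5)
  ## end-to-end determinism under one master seed
  res2 <- run_screen(reg, screen_config(), seed = 42)
  expect_identical(res$hits, res2$hits)
})

test_that("reversal mode keeps vehicle wells differentiated and reverts with drug", {
  reg <- generate_compound_library(5, frac_active = 1,
                                   potency_range = c(200, 200),
                                   efficacy_range = c(1, 1), frac_toxic = 0,
                                   seed = 2)
  layout <- generate_plate_layout(8, 12, ipqa_design())
  conc <- 10000 / 4^(0:7)
  layout <- assign_compounds(layout, rep("CPD0001", 8), conc)
  cfg <- screen_config(mode = "reversal")
  out <- run_reversal_mode(layout[layout$role != "sample" |
                                    !is.na(layout$compound_id), ],
                           reg, cfg, seed = 9)
  ## vehicle (TGF-pulsed, compound-free) wells stay myofibroblast-like
  veh <- out$percent_effect[out$role == "neg_control"]
  expect_lt(abs(mean(veh)), 5)
  ## saturating reverser returns the alpha-SMA ratio to the untreated level
  base_ratio <- mean(out$ratio_acta[out$role == "pos_control"])
  top_conc <- out[!is.na(out$compound_id) & out$conc_nM == max(conc), ]
  expect_lt(abs(top_conc$ratio_acta / base_ratio - 1), 0.35)
  expect_error(run_reversal_mode(layout, reg, screen_config(), seed = 1),
               "reversal")
})

test_that("a reverser dilution series round-trips its programmed IC50", {
  cpd <- list(compound_id = "RV", true_ic50_nM = 200, efficacy = 1,
              toxic = FALSE, tox_ec50_nM = NA, reversal_ic50_nM = 200)
  conc <- 10000 / 3^(0:7)
  f_neg <- differentiation_fraction(5)
  f_pos <- differentiation_fraction(0)
  y <- vapply(seq_along(conc), function(j) {
    fw <- simulate_well_fraction(5, cpd, conc[j], mode = "reversal",
                                 seed = derive_seed(9, "rv", j))
    percent_inhibition(fw, f_neg, f_pos)
  }, numeric(1))
  fit <- fit_3pl(log10(conc), y, "ascending")
  expect_lt(abs(log2(10^fit$logec50 / 200)), 1)  # within 2-fold
})
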