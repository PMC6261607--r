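#!/usr/bin/env Rscript
## Step 5 -- primary screen, confirmation, cross-readout correlation and
## reversal mode.
##
## Screens a 200-compound library (20 true actives) at 10 uM, applies the
## >50% effect and <50% viability-reduction filters, confirms primary
## hits by concentration response, correlates compound potencies across
## readouts, and runs the reversal (de-differentiation) protocol on a
## dilution series.

suppressMessages(library(myoscreen))
dir.create("results", showWarnings = FALSE)
seed <- 1L

## --- primary screen + confirmation --------------------------------------
registry <- generate_compound_library(200, frac_active = 0.1,
                                      potency_range = c(10, 1000),
                                      seed = derive_seed(seed, "screenlib"))
res <- run_screen(registry, screen_config(), seed = derive_seed(seed, "screen"))
hits <- res$hits
write.csv(hits, "results/screen_hits.csv", row.names = FALSE)

called <- hits$tier %in% c("primary", "confirmed")
keep <- registry$active & !registry$toxic
cat(sprintf("screened %d compounds: %d primary, %d confirmed\n",
            nrow(hits), sum(hits$tier == "primary") +
              sum(hits$tier == "confirmed"),
            sum(hits$tier == "confirmed")))
cat(sprintf("recall (non-toxic actives): %.2f   FPR (inactives): %.3f\n",
            sum(called & keep) / sum(keep),
            sum(called & !registry$active) / sum(!registry$active)))
cat(sprintf("control Z' of the screen plate: %.2f\n", res$zprime$zprime))

## --- cross-readout potency correlation ----------------------------------
## profile 12 actives in three readouts (image fraction, impedance 20 h,
## alpha-SMA ratio) and correlate the fitted IC50s, Table-2 style
prof <- registry[registry$active & !registry$toxic, ][1:12, ]
conc <- 10000 / 3^(0:7)
kp <- kinetic_params(noise_sd = 0.01)
f_neg <- differentiation_fraction(5); f_pos <- differentiation_fraction(0)
pot <- t(vapply(seq_len(nrow(prof)), function(i) {
  cpd <- prof[i, ]
  y_hca <- vapply(seq_along(conc), function(j) {
    fw <- simulate_well_fraction(5, cpd, conc[j],
                                 seed = derive_seed(seed, cpd$compound_id, "h", j))
    percent_inhibition(fw, f_neg, f_pos)
  }, numeric(1))
  y_imp <- vapply(seq_along(conc), function(j) {
    tr <- simulate_impedance_trace(5, cpd, conc[j], seq(0, 48, 0.5), kp,
                                   seed = derive_seed(seed, cpd$compound_id, "i", j))
    b <- simulate_impedance_trace(0, NULL, 0, seq(0, 48, 0.5), kp,
                                  seed = derive_seed(seed, cpd$compound_id, "ib", j))
    trace_response(preprocess_trace(tr, 0, b), 20)
  }, numeric(1))
  y_ms <- vapply(seq_along(conc), function(j) {
    q <- normalize_to_tubulin(
      simulate_msms_well(5, cpd, conc[j],
                         seed = derive_seed(seed, cpd$compound_id, "m", j)))
    q$ratio_acta
  }, numeric(1))
  c(hca = fit_3pl(log10(conc), y_hca, "ascending")$ec50,
    impedance = fit_3pl(log10(conc), y_imp, "descending")$ec50,
    msms_acta = fit_3pl(log10(conc), y_ms, "descending")$ec50)
}, numeric(3)))
rownames(pot) <- prof$compound_id
write.csv(pot, "results/readout_potencies.csv")
cr <- correlate_readouts(pot)
write.csv(cr$r, "results/readout_spearman_r.csv")
cat("\nSpearman r between readout IC50s (12 actives):\n")
print(round(cr$r, 3))
cat("two-tailed p values:\n")
print(signif(cr$p, 2))

## --- reversal mode -------------------------------------------------------
rev_reg <- generate_compound_library(1, frac_active = 1,
                                     potency_range = c(200, 200),
                                     efficacy_range = c(1, 1),
                                     frac_toxic = 0, seed = 3)
layout <- generate_plate_layout(8, 12, ipqa_design())
layout <- assign_compounds(layout, rep(rev_reg$compound_id, 8), conc)
used <- layout[layout$role != "sample" | !is.na(layout$compound_id), ]
rev <- run_reversal_mode(used, rev_reg, screen_config(mode = "reversal"),
                         seed = derive_seed(seed, "reversal"))
write.csv(rev, "results/reversal_readouts.csv", row.names = FALSE)
veh <- rev$percent_effect[rev$role == "neg_control"]
cat(sprintf("\nreversal mode: vehicle wells %.1f%% effect at 96 h (state persists)\n",
            mean(veh)))
smp <- rev[!is.na(rev$compound_id), ]
fit_rev <- fit_3pl(log10(smp$conc_nM), smp$percent_effect, "ascending")
cat(sprintf("reverser IC50 from 96 h readout: %.0f nM (programmed 200 nM)\n",
            fit_rev$ec50))
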