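test_that("plate layouts honor the control design", {
  hca <- generate_plate_layout(16, 24, hca_design())
  expect_equal(nrow(hca), 384L)
  expect_equal(sum(hca$role == "neg_control"), 32L)
  expect_equal(sum(hca$role == "pos_control"), 32L)
  ## negative controls: stimulated, compound-free; positives: unstimulated
  expect_true(all(hca$tgf_ng_ml[hca$role == "neg_control"] == 5))
  expect_true(all(is.na(hca$compound_id[hca$role == "neg_control"])))
  expect_true(all(hca$tgf_ng_ml[hca$role == "pos_control"] == 0))

  ipqa <- generate_plate_layout(8, 12, ipqa_design())
  expect_equal(nrow(ipqa), 96L)
  expect_true(all(c("neg_control", "pos_control", "baseline", "sample") %in%
                    ipqa$role))
  expect_identical(generate_plate_layout(8, 12, ipqa_design()), ipqa)

  expect_error(generate_plate_layout(
    8, 12, list(neg_cols = 1, pos_cols = integer(), baseline_cols = integer(),
                tgf_dose = 5)), "pos_control")
})

test_that("compound plating fills sample wells with replicate indices", {
  layout <- generate_plate_layout(8, 12, ipqa_design())
  layout <- assign_compounds(layout, rep(c("X1", "X2"), each = 4),
                             conc_nM = c(1000, 100, 10, 1))
  x1 <- layout[!is.na(layout$compound_id) & layout$compound_id == "X1", ]
  expect_equal(nrow(x1), 4L)
  expect_equal(sort(x1$replicate), 1:4)
  expect_true(all(x1$role == "sample"))
})

test_that("compound registries are sized, bounded and reproducible", {
  big <- generate_compound_library(1585, seed = 3)
  expect_equal(nrow(big), 1585L)
  none <- generate_compound_library(50, frac_active = 0, seed = 1)
  expect_equal(sum(none$active), 0L)
  reg1 <- generate_compound_library(200, frac_active = 0.1, seed = 7)
  reg2 <- generate_compound_library(200, frac_active = 0.1, seed = 7)
  expect_equal(sum(reg1$active), 20L)
  expect_identical(reg1, reg2)
  act <- reg1[reg1$active, ]
  expect_true(all(act$true_ic50_nM > 0))
  expect_true(all(act$efficacy >= 0 & act$efficacy <= 1))
  expect_error(generate_compound_library(10, frac_active = 0.5,
                                         potency_range = c(10, 1)),
               "potency range")
})

test_that("rendered fields carry exact ground truth and class contrast", {
  ## one large default-density field: 750 cells as seeded per well
  f <- simulate_cell_field(750, frac_myo = 0.5, dim = c(1024, 1024),
                           seed = 17)
  expect_equal(nrow(f$truth), 750L)
  expect_equal(max(f$cell_mask), 750L)
  ## conservation: every nucleus is a distinct rendered component
  comp <- EBImage::bwlabel(f$nucleus_mask > 0)
  expect_equal(max(comp), 750L)
  ## class contrast: background-subtracted alpha-SMA mask means differ by
  ## the configured factor within 10%
  p <- phenotype_params()
  a <- f$image[, , 2] - p$background
  cm <- tapply(a[f$cell_mask > 0], f$cell_mask[f$cell_mask > 0], mean)
  ratio <- mean(cm[f$truth$class == "myofibroblast"]) /
    mean(cm[f$truth$class == "fibroblast"])
  target <- p$myofibroblast$asma_mean / p$fibroblast$asma_mean
  expect_gt(ratio, target * 0.9); expect_lt(ratio, target * 1.1)
})

test_that("degenerate mixtures and bad inputs are handled", {
  f <- simulate_cell_field(30, frac_myo = 1, dim = c(224, 224), seed = 2)
  expect_true(all(f$truth$class == "myofibroblast"))
  f0 <- simulate_cell_field(0, frac_myo = 0.5, dim = c(128, 128), seed = 1)
  expect_equal(nrow(f0$truth), 0L)
  expect_error(simulate_cell_field(-1, 0.5), ">= 0")
  expect_error(simulate_cell_field(5, 0.5, dim = c(16, 16)), "smaller")
})

test_that("field generation is bit-reproducible from its seed", {
  f1 <- simulate_cell_field(25, frac_myo = 0.4, dim = c(192, 192), seed = 99)
  f2 <- simulate_cell_field(25, frac_myo = 0.4, dim = c(192, 192), seed = 99)
  expect_identical(f1$image, f2$image)
  expect_identical(f1$truth, f2$truth)
  expect_identical(f1$cell_mask, f2$cell_mask)
})

test_that("fields survive a TIFF round trip", {
  f <- simulate_cell_field(10, frac_myo = 0.5, dim = c(128, 128), seed = 4)
  path <- withr::local_tempfile(fileext = ".tif")
  write_field_tiff(f, path)
  back <- read_field_tiff(path)
  expect_equal(dim(back), dim(f$image))
  expect_equal(back, f$image, ignore_attr = TRUE)
})

test_that("MRM well generator reproduces its programmed dose response", {
  ## no induction without TGF, exactly baseline without noise
  mp <- msms_params()
  q0 <- normalize_to_tubulin(simulate_msms_well(0, noise = FALSE))
  expect_equal(q0$ratio_acta, mp$baseline_ratio_acta)
  expect_equal(q0$ratio_col1, mp$baseline_ratio_col1)
  ## saturating dose: ~3-fold induction
  qs <- normalize_to_tubulin(simulate_msms_well(5, noise = FALSE))
  expect_equal(qs$ratio_acta / q0$ratio_acta,
               1 + (mp$fold - 1) * hill(5, mp$ec50_acta), tolerance = 1e-12)
  expect_gt(qs$ratio_acta / q0$ratio_acta, 2.9)
  ## round trip: noiseless dose series refit with the 3PL recovers EC50
  d <- c(0.0078, 0.0156, 0.03125, 0.0625, 0.125, 0.25, 0.5, 1, 2, 5)
  r <- vapply(d, function(dd) {
    q <- normalize_to_tubulin(simulate_msms_well(dd, noise = FALSE))
    q$ratio_acta
  }, numeric(1))
  fit <- fit_3pl(log10(d), r)
  expect_lt(abs(10^fit$logec50 - mp$ec50_acta), 1e-3)
  expect_error(simulate_msms_well(5, n_cells = 0), "> 0")
})

test_that("noiseless readouts are monotone in dose and compound concentration", {
  doses <- c(0, 0.01, 0.05, 0.1, 0.5, 1, 5)
  fr <- vapply(doses, differentiation_fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
  ra <- vapply(doses, function(d)
    normalize_to_tubulin(simulate_msms_well(d, noise = FALSE))$ratio_acta,
    numeric(1))
  expect_true(all(diff(ra) >= 0))
  cpd <- list(true_ic50_nM = 100, efficacy = 1)
  concs <- c(0, 1, 10, 100, 1000, 1e4, 1e5)
  fc <- vapply(concs, function(cc)
    differentiation_fraction(5, cpd, cc), numeric(1))
  expect_true(all(diff(fc) <= 0))
  ac <- vapply(concs, function(cc)
    impedance_amplitude(5, kinetic_params(), cpd, cc), numeric(1))
  expect_true(all(diff(ac) <= 0))
})
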