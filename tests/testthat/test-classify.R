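test_that("indistinguishable control populations score at chance level", {
  toy <- toy_feature_plate(n_per_class = 150, delta = 0, sdev = 1, seed = 2)
  m <- train_classifier(toy$features, toy$layout, k = 10, seed = 1)
  expect_gt(m$cv_accuracy, 0.35)
  expect_lt(m$cv_accuracy, 0.65)
})

test_that("a cleanly separated toy set matches a nearest-centroid oracle", {
  toy <- toy_feature_plate(n_per_class = 60, delta = 10, sdev = 0.1,
                           p = 2, seed = 3)
  m <- train_classifier(toy$features, toy$layout, k = 10, seed = 1)
  expect_equal(m$cv_accuracy, 1.0)
  cl <- classify_cells(m, toy$features)
  ## nearest-centroid oracle on the same points
  X <- as.matrix(toy$features[, c("f1", "f2")])
  mu_myo <- colMeans(X[toy$truth == "myofibroblast", ])
  mu_fib <- colMeans(X[toy$truth == "fibroblast", ])
  oracle <- ifelse(
    rowSums((X - matrix(mu_myo, nrow(X), 2, byrow = TRUE))^2) <
      rowSums((X - matrix(mu_fib, nrow(X), 2, byrow = TRUE))^2),
    "myofibroblast", "fibroblast")
  expect_equal(cl$label, oracle)
  ## decision sign is consistent with the label
  expect_true(all((cl$decision > 0) == (cl$label == "myofibroblast")))
})

test_that("training validates its inputs", {
  toy <- toy_feature_plate(n_per_class = 30, seed = 4)
  single <- toy$layout
  single$role <- "neg_control"
  expect_error(train_classifier(toy$features, single, k = 5), "single class")
  expect_error(train_classifier(toy$features, toy$layout, k = 50),
               "at least k")
})

test_that("feature weights rank deterministically with ties by name", {
  m <- structure(list(w = c(f1 = 0, f2 = 5, f3 = -2)),
                 class = "myo_classifier")
  r <- rank_feature_weights(m)
  expect_equal(r$feature, c("f2", "f3", "f1"))
  tie <- structure(list(w = c(b = 0, a = 0, c = 0)),
                   class = "myo_classifier")
  expect_equal(rank_feature_weights(tie)$feature, c("a", "b", "c"))
  expect_error(rank_feature_weights(structure(list(w = NULL),
                                             class = "myo_classifier")),
               "untrained")
  ## on the default 384-well plate an alpha-SMA granularity or texture
  ## feature is among the 10 most informative
  acc <- acceptance_plate()
  top10 <- rank_feature_weights(acc$model)$feature[1:10]
  expect_true(any(grepl("^asma_(gran|glcm)", top10)))
})

test_that("classification propagates labels, errors and empty tables", {
  toy <- toy_feature_plate(n_per_class = 40, delta = 5, seed = 6)
  m <- train_classifier(toy$features, toy$layout, k = 5, seed = 1)
  ## duplicate of a training myofibroblast cell keeps its label
  dup <- toy$features[1, ]
  expect_equal(classify_cells(m, dup)$label, "myofibroblast")
  empty <- toy$features[0, ]
  expect_equal(nrow(classify_cells(m, empty)), 0L)
  bad <- toy$features
  names(bad)[names(bad) == "f1"] <- "g1"
  expect_error(classify_cells(m, bad), "match")
})

test_that("training twice with one seed reproduces identical weights", {
  plate <- small_control_plate()
  m1 <- train_classifier(plate$features, plate$layout, k = 5, seed = 77)
  m2 <- train_classifier(plate$features, plate$layout, k = 5, seed = 77)
  expect_identical(m1$w, m2$w)
  expect_identical(m1$cv_accuracy, m2$cv_accuracy)
})

test_that("resubstitution accuracy does not fall below CV accuracy", {
  plate <- small_control_plate()
  m <- train_classifier(plate$features, plate$layout, k = 5, seed = 8)
  cl <- classify_cells(m, plate$features)
  roles <- setNames(plate$layout$role, plate$layout$well)
  want <- ifelse(roles[cl$well] == "neg_control", "myofibroblast",
                 "fibroblast")
  train_acc <- mean(cl$label == want)
  expect_gte(train_acc, m$cv_accuracy - 0.02)
})

test_that("percent effect anchors at the control means and interpolates", {
  layout <- data.frame(well = c("N1", "N2", "P1", "P2", "S1"),
                       role = c("neg_control", "neg_control",
                                "pos_control", "pos_control", "sample"))
  mk <- function(well, f, n = 100) data.frame(
    well = well, label = rep(c("myofibroblast", "fibroblast"),
                             c(round(f * n), n - round(f * n))))
  labels <- rbind(mk("N1", 0.9), mk("N2", 0.9), mk("P1", 0.1), mk("P2", 0.1),
                  mk("S1", 0.5))
  eff <- well_percent_effect(labels, layout)
  expect_equal(eff$percent_effect[eff$well == "N1"], 0)
  expect_equal(eff$percent_effect[eff$well == "P1"], 100)
  expect_equal(eff$percent_effect[eff$well == "S1"], 50)  # midway
  expect_equal(eff$fraction[eff$well == "S1"], 0.5)
  deg <- rbind(mk("N1", 0.5), mk("N2", 0.5), mk("P1", 0.5), mk("P2", 0.5))
  expect_error(well_percent_effect(deg, layout), "degenerate")
})

test_that("percent effect rises monotonically along a noiseless dilution", {
  cpd <- list(true_ic50_nM = 50, efficacy = 1)
  f_neg <- differentiation_fraction(5)
  f_pos <- differentiation_fraction(0)
  conc <- c(0.1, 1, 10, 100, 1000, 1e4)
  eff <- vapply(conc, function(cc) {
    percent_inhibition(differentiation_fraction(5, cpd, cc), f_neg, f_pos)
  }, numeric(1))
  expect_true(all(diff(eff) > 0))
})

test_that("models survive a JSON round trip", {
  toy <- toy_feature_plate(n_per_class = 40, delta = 5, seed = 10)
  m <- train_classifier(toy$features, toy$layout, k = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(m, path)
  m2 <- load_classifier(path)
  expect_equal(m2$w, m$w)
  expect_equal(classify_cells(m2, toy$features)$label,
               classify_cells(m, toy$features)$label)
})
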