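.feature_cols <- function(features) {
  setdiff(names(features),
          c("well", "cell_id", "label", "class", "role", "decision"))
}

#' Train a control-anchored linear support-vector classifier
#'
#' Cells from the in-plate 0%-effect controls (5 ng/ml TGF-beta1, labelled
#' `myofibroblast`) and 100%-effect controls (no TGF-beta1, labelled
#' `fibroblast`) form the training set.  Features are standardized
#' (training mean/SD), the majority class is subsampled to balance the
#' classes, and a linear-kernel SVM is fitted; the linear decision
#' function exposes one interpretable weight per feature.  Accuracy is
#' estimated by stratified k-fold cross-validation (pooled over folds).
#'
#' @param features per-cell feature table ([extract_cell_features()]) with
#'   a `well` column.
#' @param layout [generate_plate_layout()] result mapping wells to roles.
#' @param k number of CV folds (default 10); each control class must
#'   contribute at least k cells.
#' @param seed integer seed (fold assignment and class balancing); the
#'   trained weights are reproducible from it.
#' @param cost SVM regularization constant (default 1).
#' @return Object of class `myo_classifier`: feature names,
#'   standardization parameters, weights `w`, bias `b`, `cv_accuracy`,
#'   `levels` (`fibroblast`, `myofibroblast`; decision value > 0 means
#'   myofibroblast), training metadata.
#' @export
train_classifier <- function(features, layout, k = 10, seed = 1L,
                             cost = 1) {
  roles <- setNames(layout$role, layout$well)
  role <- roles[features$well]
  train_idx <- which(role %in% c("neg_control", "pos_control"))
  if (!length(train_idx)) stop("no control-well cells in the feature table")
  lab <- ifelse(role[train_idx] == "neg_control", "myofibroblast",
                "fibroblast")
  if (length(unique(lab)) < 2L) {
    stop("training set contains a single class; both control roles needed")
  }
  if (min(table(lab)) < k) {
    stop("need at least k = ", k, " cells per control class")
  }
  cols <- .feature_cols(features)
  X <- as.matrix(features[train_idx, cols, drop = FALSE])
  y <- factor(lab, levels = c("fibroblast", "myofibroblast"))

  .with_seed(seed, {
    ## balance: subsample the majority control class
    n_min <- min(table(y))
    keep <- unlist(lapply(levels(y), function(lv) {
      i <- which(y == lv)
      if (length(i) > n_min) sort(sample(i, n_min)) else i
    }))
    X <- X[keep, , drop = FALSE]; y <- y[keep]

    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0] <- 1
    Xs <- scale(X, ctr, scl)

    ## stratified fold assignment
    fold <- integer(length(y))
    for (lv in levels(y)) {
      i <- which(y == lv)
      fold[i] <- sample(rep_len(seq_len(k), length(i)))
    }
    correct <- 0L
    for (f in seq_len(k)) {
      te <- fold == f
      m <- e1071::svm(Xs[!te, , drop = FALSE], y[!te], kernel = "linear",
                      cost = cost, scale = FALSE)
      correct <- correct + sum(predict(m, Xs[te, , drop = FALSE]) == y[te])
    }
    cv_acc <- correct / length(y)

    m <- e1071::svm(Xs, y, kernel = "linear", cost = cost, scale = FALSE)
    w <- drop(t(m$coefs) %*% m$SV)
    b <- -m$rho
    ## orient the decision value so positive means myofibroblast
    dec1 <- drop(Xs[1, ] %*% w) + b
    pred1 <- as.character(predict(m, Xs[1, , drop = FALSE]))
    flip <- (dec1 > 0) != (pred1 == "myofibroblast")
    if (flip) { w <- -w; b <- -b }

    structure(list(
      feature_names = cols, center = ctr, scale = scl,
      w = setNames(w, cols), b = b,
      levels = c("fibroblast", "myofibroblast"),
      cv_accuracy = cv_acc, k = k, cost = cost, seed = seed,
      n_train = length(y),
      control_wells = sort(unique(features$well[train_idx]))
    ), class = "myo_classifier")
  })
}

#' @export
print.myo_classifier <- function(x, ...) {
  cat(sprintf(
    "<myo_classifier> linear SVM, %d features, %d training cells, %d-fold CV accuracy %.3f\n",
    length(x$w), x$n_train, x$k, x$cv_accuracy))
  invisible(x)
}

#' Rank features by classifier weight
#'
#' Features sorted by decreasing absolute linear weight (ties broken
#' deterministically by feature name).  A high rank means the feature
#' contributed strongly to separating fibroblasts from myofibroblasts.
#'
#' @param model a trained [train_classifier()] model.
#' @return data.frame `rank`, `feature`, `weight`, `abs_weight`.
#' @export
rank_feature_weights <- function(model) {
  if (!inherits(model, "myo_classifier") || is.null(model$w)) {
    stop("untrained or invalid classifier model")
  }
  o <- order(-abs(model$w), names(model$w))
  data.frame(rank = seq_along(o), feature = names(model$w)[o],
             weight = unname(model$w[o]), abs_weight = abs(unname(model$w[o])),
             stringsAsFactors = FALSE)
}

#' Classify every cell of a feature table
#'
#' Applies the standardized linear decision function; the label is
#' `myofibroblast` when the decision value is positive.
#'
#' @param model [train_classifier()] model.
#' @param features feature table whose feature columns match training.
#' @return data.frame `well`, `cell_id`, `decision`, `label`.
#' @export
classify_cells <- function(model, features) {
  stopifnot(inherits(model, "myo_classifier"))
  if (nrow(features) == 0L) {
    return(data.frame(well = character(), cell_id = integer(),
                      decision = numeric(), label = character()))
  }
  if (!all(model$feature_names %in% names(features))) {
    stop("feature table does not match the model's training features")
  }
  X <- as.matrix(features[, model$feature_names, drop = FALSE])
  Xs <- scale(X, model$center, model$scale)
  dec <- drop(Xs %*% model$w) + model$b
  data.frame(well = features$well, cell_id = features$cell_id,
             decision = dec,
             label = ifelse(dec > 0, "myofibroblast", "fibroblast"),
             stringsAsFactors = FALSE)
}

#' Aggregate per-cell labels to per-well percent effect
#'
#' Per well, the myofibroblast fraction `f` is rescaled against the
#' in-plate control means: `percent_effect = 100 * (f_neg - f) /
#' (f_neg - f_pos)`, so the TGF-beta1 control scores 0 and the untreated
#' control 100.  Both the raw fraction and the (unclipped) percent effect
#' are returned; `clip = TRUE` truncates to `[0, 100]` for reporting.
#'
#' @param labels data.frame from [classify_cells()] (columns `well`,
#'   `label`).
#' @param layout plate layout with control roles.
#' @param clip clip percent effect to `[0, 100]`.
#' @return data.frame `well`, `role`, `n_cells`, `fraction`,
#'   `percent_effect`.
#' @export
well_percent_effect <- function(labels, layout, clip = FALSE) {
  stopifnot(all(c("well", "label") %in% names(labels)))
  agg <- stats::aggregate(
    list(fraction = labels$label == "myofibroblast"),
    by = list(well = labels$well), FUN = mean)
  agg$n_cells <- as.integer(table(labels$well)[agg$well])
  roles <- setNames(layout$role, layout$well)
  agg$role <- unname(roles[agg$well])
  f_neg <- mean(agg$fraction[agg$role == "neg_control"])
  f_pos <- mean(agg$fraction[agg$role == "pos_control"])
  if (!is.finite(f_neg) || !is.finite(f_pos)) {
    stop("both control roles must be present among the classified wells")
  }
  if (f_neg == f_pos) stop("degenerate controls: f_neg == f_pos")
  agg$percent_effect <- 100 * (f_neg - agg$fraction) / (f_neg - f_pos)
  if (clip) agg$percent_effect <- .clamp(agg$percent_effect, 0, 100)
  agg[, c("well", "role", "n_cells", "fraction", "percent_effect")]
}

#' Serialize / restore a classifier model as JSON
#'
#' Flat-text model exchange: feature names, standardization parameters,
#' weights, bias and CV accuracy.
#'
#' @param model [train_classifier()] model.
#' @param path JSON file path.
#' @return `save_classifier` invisibly returns `path`; `load_classifier`
#'   the restored model.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "myo_classifier"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$center <- setNames(as.numeric(x$center), x$feature_names)
  x$scale <- setNames(as.numeric(x$scale), x$feature_names)
  x$w <- setNames(as.numeric(x$w), x$feature_names)
  structure(x, class = "myo_classifier")
}

#' Simulate and analyse the control wells of an HCA plate
#'
#' Streams over the control wells of a plate layout: renders each well's
#' field ([simulate_cell_field()]) with hierarchical per-well seeds,
#' segments it and extracts features, discarding the raster afterwards.
#' Control-well fractions receive the generator's default well-to-well
#' variability (truncated Gaussian, SD `fraction_sd` on the fraction
#' scale, i.e. 2.5 percent-effect units by default).
#'
#' @param layout plate layout; only `neg_control`/`pos_control` wells are
#'   simulated unless `roles` says otherwise.
#' @param cells_per_well cells rendered per well.
#' @param seed master plate seed.
#' @param params [phenotype_params()].
#' @param config [feature_config()].
#' @param dim field size in pixels.
#' @param fraction_sd well-level SD of the latent myofibroblast fraction.
#' @param roles roles to simulate.
#' @return list with `features` (all wells pooled), `truth`, `layout`.
#' @export
simulate_hca_controls <- function(layout, cells_per_well = 40, seed = 1L,
                                  params = phenotype_params(),
                                  config = feature_config(),
                                  dim = c(256, 256), fraction_sd = 0.025,
                                  roles = c("neg_control", "pos_control")) {
  wells <- layout[layout$role %in% roles, , drop = FALSE]
  feats <- vector("list", nrow(wells))
  truth <- vector("list", nrow(wells))
  for (i in seq_len(nrow(wells))) {
    w <- wells[i, ]
    f0 <- differentiation_fraction(w$tgf_ng_ml)
    fw <- .with_seed(derive_seed(seed, w$well, "frac"),
                     .clamp(f0 + rnorm(1, 0, fraction_sd), 0, 1))
    fld <- simulate_cell_field(cells_per_well, frac_myo = fw,
                               params = params, dim = dim,
                               seed = derive_seed(seed, w$well, "field"),
                               well = w$well)
    pf <- process_field(fld, config, well = w$well)
    feats[[i]] <- pf$features
    truth[[i]] <- fld$truth
  }
  list(features = do.call(rbind, feats), truth = do.call(rbind, truth),
       layout = layout)
}
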