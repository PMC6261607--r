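#' Feature-extraction configuration
#'
#' @param scales granularity disc radii (px).
#' @param glcm_distances co-occurrence offsets (px); 4 orientations are
#'   pooled per distance.
#' @param n_grey grey levels for co-occurrence quantization.
#' @param tophat_radius white top-hat radius for background correction
#'   (default twice the largest granularity scale).
#' @param drop_edge_cells drop cells touching the raster border (kept by
#'   default).
#' @return Configuration list for [extract_cell_features()].
#' @export
feature_config <- function(scales = 1:8, glcm_distances = c(1, 3),
                           n_grey = 32, tophat_radius = 2 * max(scales),
                           drop_edge_cells = FALSE) {
  list(scales = scales, glcm_distances = glcm_distances, n_grey = n_grey,
       tophat_radius = tophat_radius, drop_edge_cells = drop_edge_cells)
}

## per-cell intensity statistics on background-corrected counts
.intensity_features <- function(values, labels, prefix) {
  dt <- data.table::data.table(cell = labels, v = values)
  f <- dt[, {
    v <- v
    m <- mean(v); s <- if (length(v) > 1) sd(v) else 0
    q <- quantile(v, c(.05, .1, .25, .5, .75, .9, .95), names = FALSE,
                  type = 7)
    z3 <- if (s > 0) mean(((v - m) / s)^3) else 0
    z4 <- if (s > 0) mean(((v - m) / s)^4) - 3 else 0
    list(
      int_mean = m, int_sd = s, int_mad = mad(v), int_min = min(v),
      int_max = max(v), int_q05 = q[1], int_q10 = q[2], int_q25 = q[3],
      int_q50 = q[4], int_q75 = q[5], int_q90 = q[6], int_q95 = q[7],
      int_iqr = q[5] - q[3], int_cv = if (m > 0) s / m else 0,
      int_skew = z3, int_kurt = z4, int_integrated = sum(v),
      int_bright_frac = if (s > 0) mean(v > m + 2 * s) else 0,
      int_p90_over_mean = if (m > 0) q[6] / m else 0
    )
  }, by = cell]
  data.table::setnames(f, setdiff(names(f), "cell"),
                       paste0(prefix, "_", setdiff(names(f), "cell")))
  f
}

## per-cell granularity fractions from a whole-image opening series
.granularity_features <- function(bc01, cells, scales, prefix) {
  fg <- cells > 0L
  lab <- cells[fg]
  n <- max(cells)
  total <- rowsum(bc01[fg], lab)
  tot <- numeric(n); tot[as.integer(rownames(total))] <- total
  series <- .opening_series(bc01, scales)
  prev <- bc01
  out <- matrix(0, n, length(scales),
                dimnames = list(NULL, paste0(prefix, "_gran_s", scales)))
  for (i in seq_along(scales)) {
    d <- (prev - series[[i]])[fg]
    s <- rowsum(d, lab)
    v <- numeric(n); v[as.integer(rownames(s))] <- s
    out[, i] <- ifelse(tot > 0, 100 * pmax(v, 0) / tot, 0)
    prev <- series[[i]]
  }
  data.table::data.table(cell = seq_len(n), out)
}

## pooled symmetric grey-level co-occurrence statistics at one distance
.glcm_features <- function(qimg, cells, d, prefix) {
  H <- nrow(qimg); W <- ncol(qimg)
  offs <- list(c(0L, d), c(d, 0L), c(d, d), c(-d, d))
  labs <- a <- b <- vector("list", length(offs))
  for (k in seq_along(offs)) {
    dr <- offs[[k]][1]; dc <- offs[[k]][2]
    r1 <- max(1L, 1L - dr):min(H, H - dr)
    c1 <- max(1L, 1L - dc):min(W, W - dc)
    la <- cells[r1, c1, drop = FALSE]
    lb <- cells[r1 + dr, c1 + dc, drop = FALSE]
    keep <- la == lb & la > 0L
    labs[[k]] <- la[keep]
    a[[k]] <- qimg[r1, c1, drop = FALSE][keep]
    b[[k]] <- qimg[r1 + dr, c1 + dc, drop = FALSE][keep]
  }
  dt <- data.table::data.table(cell = unlist(labs),
                               a = unlist(a), b = unlist(b))
  n <- max(cells)
  base <- data.table::data.table(cell = seq_len(n))
  if (nrow(dt) == 0L) {
    for (nm in c("contrast", "homogeneity", "correlation", "energy",
                 "entropy")) {
      base[[paste0(prefix, "_glcm", d, "_", nm)]] <- 0
    }
    return(base)
  }
  s1 <- dt[, {
    sa <- sd(a); sb <- sd(b)
    list(contrast = mean((a - b)^2),
         homogeneity = mean(1 / (1 + abs(a - b))),
         correlation = if (!is.na(sa) && sa > 0 && sb > 0) cor(a, b) else 0)
  }, by = cell]
  s2 <- dt[, .(n = .N), by = .(cell, a, b)][
    , p := n / sum(n), by = cell][
    , .(energy = sum(p^2), entropy = -sum(p * log(p))), by = cell]
  out <- merge(merge(base, s1, by = "cell", all.x = TRUE),
               s2, by = "cell", all.x = TRUE)
  for (nm in c("contrast", "homogeneity", "correlation", "energy",
               "entropy")) {
    out[is.na(out[[nm]]), (nm) := 0]
    data.table::setnames(out, nm, paste0(prefix, "_glcm", d, "_", nm))
  }
  out[order(cell)]
}

## fraction of signal in three concentric zones around the nucleus centroid
.radial_features <- function(bc, cells, centers, prefix) {
  n <- max(cells)
  fg <- which(cells > 0L, arr.ind = TRUE)
  lab <- cells[fg]
  dy <- fg[, 1] - centers[lab, 2]
  dx <- fg[, 2] - centers[lab, 1]
  dist <- sqrt(dx^2 + dy^2)
  rmax <- tapply(dist, lab, max)
  rm <- rep(1, n); rm[as.integer(names(rmax))] <- pmax(rmax, 1e-6)
  bin <- pmin(floor(3 * dist / rm[lab]) + 1L, 3L)
  v <- bc[fg]
  tot <- rowsum(v, lab)
  totv <- numeric(n); totv[as.integer(rownames(tot))] <- tot
  out <- matrix(0, n, 3,
                dimnames = list(NULL, paste0(prefix, "_radial_", 1:3)))
  for (k in 1:3) {
    s <- rowsum(v * (bin == k), lab)
    vv <- numeric(n); vv[as.integer(rownames(s))] <- s
    out[, k] <- ifelse(totv > 0, vv / totv, 0)
  }
  data.table::data.table(cell = seq_len(n), out)
}

## polygon area of the convex hull of pixel centres (shoelace)
.hull_area <- function(pts) {
  if (nrow(pts) < 3L) return(nrow(pts))
  h <- chull(pts)
  xs <- pts[h, 1]; ys <- pts[h, 2]
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

.shape_features <- function(cells, nuclei) {
  n <- max(cells)
  H <- nrow(cells); W <- ncol(cells)
  fg <- which(cells > 0L, arr.ind = TRUE)
  lab <- cells[fg]
  area <- tabulate(lab, n)

  ## 4-neighbour boundary pixels (different label or image border)
  pad <- matrix(0L, H + 2, W + 2); pad[2:(H + 1), 2:(W + 1)] <- cells
  ctr <- pad[2:(H + 1), 2:(W + 1)]
  bnd <- (pad[1:H, 2:(W + 1)] != ctr) | (pad[3:(H + 2), 2:(W + 1)] != ctr) |
    (pad[2:(H + 1), 1:W] != ctr) | (pad[2:(H + 1), 3:(W + 2)] != ctr)
  perim <- tabulate(ctr[bnd & ctr > 0L], n)

  nuc_area <- tabulate(nuclei[nuclei > 0L], n)
  edge <- rep(0, n)
  edge_ids <- unique(c(cells[1, ], cells[H, ], cells[, 1], cells[, W]))
  edge[edge_ids[edge_ids > 0L]] <- 1

  major <- minor <- ecc <- solidity <- extent <- numeric(n)
  for (i in seq_len(n)) {
    pts <- fg[lab == i, , drop = FALSE]
    if (nrow(pts) == 0L) next
    if (nrow(pts) == 1L) {
      major[i] <- minor[i] <- 1; solidity[i] <- 1; extent[i] <- 1
      next
    }
    cv <- stats::cov(pts)
    ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
    major[i] <- 4 * sqrt(ev[1]); minor[i] <- 4 * sqrt(ev[2])
    ecc[i] <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0
    ## hull of pixel centres underestimates the pixelated region by about
    ## half the perimeter; correct so convex masks score ~1
    ha <- .hull_area(pts[, c(2, 1), drop = FALSE]) + perim[i] / 2 + 1
    solidity[i] <- min(area[i] / ha, 1)
    bb <- (diff(range(pts[, 1])) + 1) * (diff(range(pts[, 2])) + 1)
    extent[i] <- area[i] / bb
  }
  data.table::data.table(
    cell = seq_len(n), shape_area = area, shape_perimeter = perim,
    shape_form_factor = ifelse(perim > 0, 4 * pi * area / perim^2, 0),
    shape_major_axis = major, shape_minor_axis = minor,
    shape_eccentricity = ecc, shape_solidity = solidity,
    shape_extent = extent, shape_nucleus_area = nuc_area,
    shape_nuc_cyto_ratio = ifelse(area > 0, nuc_area / area, 0),
    shape_edge = edge
  )
}

#' Extract per-cell feature vectors from a segmented well image
#'
#' Computes, per cell and per marker channel (alpha-SMA and FN):
#' intensity statistics, the morphological granularity spectrum,
#' grey-level co-occurrence texture (contrast, homogeneity, correlation,
#' energy, entropy at the configured offsets, 4 orientations pooled) and
#' radial signal distribution -- all on background-corrected intensities
#' (white top-hat) -- plus channel-independent shape descriptors (area,
#' perimeter, form factor, axes, eccentricity, solidity, extent, nucleus
#' area).  Around 90 features per cell; every value is finite.
#'
#' @param image rows x cols x 4 array of counts (channel order DAPI,
#'   alpha-SMA, FN, whole-cell).
#' @param cells integer cell label matrix ([segment_cells()]).
#' @param nuclei integer nucleus label matrix sharing the cell labels.
#' @param config [feature_config()] list.
#' @param well well id recorded in the table.
#' @return data.frame: `well`, `cell_id`, then one column per feature
#'   (channel-prefixed names `asma_*`, `fn_*`, `shape_*`).
#' @export
extract_cell_features <- function(image, cells, nuclei,
                                  config = feature_config(), well = "W01") {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] >= 4L)
  if (!all(dim(image)[1:2] == dim(cells)) ||
      !all(dim(cells) == dim(nuclei))) {
    stop("image, cell and nucleus rasters must share the same shape")
  }
  n <- max(cells)
  if (n == 0L) {
    return(data.frame(well = character(), cell_id = integer()))
  }

  ## nucleus centroids (fall back to cell centroid if a nucleus is missing)
  centers <- matrix(NA_real_, n, 2)
  idx <- which(nuclei > 0L, arr.ind = TRUE)
  if (nrow(idx)) {
    l <- nuclei[idx]
    centers[sort(unique(l)), 2] <- tapply(idx[, 1], l, mean)
    centers[sort(unique(l)), 1] <- tapply(idx[, 2], l, mean)
  }
  miss <- which(is.na(centers[, 1]))
  if (length(miss)) {
    idc <- which(cells > 0L, arr.ind = TRUE)
    lc <- cells[idc]
    cy <- tapply(idc[, 1], lc, mean); cx <- tapply(idc[, 2], lc, mean)
    centers[miss, 2] <- cy[as.character(miss)]
    centers[miss, 1] <- cx[as.character(miss)]
  }

  feats <- .shape_features(cells, nuclei)
  fgidx <- cells > 0L
  lab <- cells[fgidx]

  brush <- EBImage::makeBrush(2L * config$tophat_radius + 1L, "disc")
  for (chan in c(asma = 2L, fn = 3L)) {
    prefix <- names(which(c(asma = 2L, fn = 3L) == chan))
    bc01 <- EBImage::whiteTopHat(.as01(image[, , chan]), brush)
    bc01 <- pmax(bc01, 0)
    bc <- bc01 * .MAXC

    fi <- .intensity_features(bc[fgidx], lab, prefix)
    fg <- .granularity_features(bc01, cells, config$scales, prefix)
    ## per-cell min-max quantization: each cell's texture is described on
    ## its own intensity range, independent of what else is in the image
    v <- bc[fgidx]
    mn <- tapply(v, lab, min); mx <- tapply(v, lab, max)
    rng <- pmax(mx - mn, 1e-9)
    qv <- pmin(floor((v - mn[as.character(lab)]) / rng[as.character(lab)] *
                       config$n_grey) + 1L, config$n_grey)
    qimg <- matrix(0L, nrow(cells), ncol(cells))
    qimg[fgidx] <- as.integer(qv)
    ftex <- lapply(config$glcm_distances,
                   function(d) .glcm_features(qimg, cells, as.integer(d),
                                              prefix))
    fr <- .radial_features(bc, cells, centers, prefix)
    for (f in c(list(fi, fg), ftex, list(fr))) {
      feats <- merge(feats, f, by = "cell", all.x = TRUE)
    }
  }
  feats <- feats[order(cell)]
  out <- as.data.frame(feats)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) ifelse(is.finite(v), v, 0))
  if (config$drop_edge_cells) out <- out[out$shape_edge == 0, , drop = FALSE]
  data.frame(well = well, cell_id = out$cell,
             out[setdiff(names(out), "cell")],
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Run segmentation and feature extraction on one synthetic field
#'
#' Convenience wrapper: [detect_nuclei()] on the DAPI channel,
#' [segment_cells()] on the whole-cell channel, then
#' [extract_cell_features()].
#'
#' @param field a [simulate_cell_field()] result (or a rows x cols x 4
#'   count array).
#' @param config [feature_config()].
#' @param well well id.
#' @return list with `features` (data.frame), `nuclei`, `cells`
#'   (label matrices).
#' @export
process_field <- function(field, config = feature_config(), well = NULL) {
  img <- if (is.list(field)) field$image else field
  if (is.null(well)) well <- if (is.list(field) && nrow(field$truth))
    field$truth$well[1] else "W01"
  nuc <- detect_nuclei(img[, , 1])
  if (max(nuc$labels) == 0L) {
    return(list(features = data.frame(well = character(),
                                      cell_id = integer()),
                nuclei = nuc$labels, cells = nuc$labels))
  }
  cells <- segment_cells(img[, , 4], nuc$labels)
  feats <- extract_cell_features(img, cells, nuc$labels, config, well)
  list(features = feats, nuclei = nuc$labels, cells = cells)
}
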