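## EBImage grayscale morphology operates on [0, 1] data; all rasters are
## 16-bit counts, so they are scaled by 1/65535 around every call.
.MAXC <- 65535

.as01 <- function(m) m / .MAXC

#' Detect nuclei in a DAPI channel
#'
#' Gaussian smoothing, Otsu threshold, then a distance-transform watershed
#' to split touching nuclei; components below `min_area` are discarded.
#'
#' @param dapi single-channel raster (matrix of 16-bit counts).
#' @param min_area minimum nucleus area (px^2), default 30.
#' @param sigma Gaussian smoothing SD (px).
#' @return list with `labels` (integer label matrix, 1..n) and
#'   `centroids` (data.frame `nucleus`, `x`, `y`, `area`; 0-based
#'   coordinates, origin top-left).
#' @export
detect_nuclei <- function(dapi, min_area = 30, sigma = 2) {
  if (!is.matrix(dapi)) stop("dapi channel must be a 2-D raster")
  x <- .as01(dapi)
  if (max(x) <= 0) {
    return(list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
                centroids = data.frame(nucleus = integer(), x = numeric(),
                                       y = numeric(), area = numeric())))
  }
  sm <- EBImage::gblur(x, sigma = sigma)
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  mask <- sm > thr
  if (!any(mask)) {
    return(list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
                centroids = data.frame(nucleus = integer(), x = numeric(),
                                       y = numeric(), area = numeric())))
  }
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = 1)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(dapi), ncol(dapi))

  ## drop small components, relabel 1..n
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  lab[lab > 0] <- remap[lab[lab > 0]]

  if (!length(keep)) {
    return(list(labels = lab, centroids = data.frame(
      nucleus = integer(), x = numeric(), y = numeric(), area = numeric())))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  cy <- tapply(idx[, 1], l, mean)
  cx <- tapply(idx[, 2], l, mean)
  ar <- tabulate(l)
  list(labels = lab,
       centroids = data.frame(nucleus = seq_along(keep),
                              x = as.numeric(cx) - 1, y = as.numeric(cy) - 1,
                              area = ar))
}

#' Segment cells by seeded propagation from nuclei
#'
#' Otsu-thresholded foreground of the whole-cell channel, partitioned by
#' Voronoi-style propagation from the nucleus seeds (the same seeded
#' region-growing used by standard cell-profiling pipelines).  Every seed
#' yields exactly one region and regions are disjoint, so the cell count
#' equals the nucleus count.
#'
#' @param wholecell whole-cell channel raster (matrix of counts).
#' @param nucleus_seeds integer label matrix from [detect_nuclei()].
#' @param sigma Gaussian smoothing SD before thresholding.
#' @return Integer cell label matrix sharing the nucleus labels.
#' @export
segment_cells <- function(wholecell, nucleus_seeds, sigma = 2) {
  if (!is.matrix(wholecell)) stop("wholecell channel must be a 2-D raster")
  stopifnot(all(dim(wholecell) == dim(nucleus_seeds)))
  if (max(nucleus_seeds) == 0L) stop("no nucleus seeds provided")
  x <- EBImage::gblur(.as01(wholecell), sigma = sigma)
  thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  mask <- x > thr | nucleus_seeds > 0L
  lab <- EBImage::propagate(EBImage::Image(x), seeds = nucleus_seeds,
                            mask = mask, lambda = 1e-4)
  matrix(as.integer(EBImage::imageData(lab)), nrow(wholecell), ncol(wholecell))
}

## pointwise-monotone opening series: successive grayscale openings with
## nested disc structuring elements, clamped so the sequence never increases
.opening_series <- function(x01, scales) {
  out <- vector("list", length(scales))
  prev <- x01
  for (i in seq_along(scales)) {
    op <- EBImage::opening(prev, EBImage::makeBrush(2L * scales[i] + 1L, "disc"))
    op <- pmin(op, prev)
    out[[i]] <- op
    prev <- op
  }
  out
}

#' Morphological granularity spectrum
#'
#' Size-resolved texture descriptor: the percentage of total signal
#' removed between successive grayscale openings with disc structuring
#' elements of increasing radius.  Entry s is large when the image
#' contains bright objects of radius about `scales[s]` -- the number and
#' size distribution of sub-cellular objects is measured without
#' segmenting them.  Entries are nonnegative and sum to at most 100.
#'
#' @param region_values raster of intensity counts (matrix); an all-zero
#'   region yields a zero vector.
#' @param scales strictly increasing disc radii (px), default 1:8.
#' @param mask optional logical matrix restricting the signal totals.
#' @return Numeric vector, one percentage per scale.
#' @examples
#' m <- matrix(0, 32, 32); m[10:14, 10:14] <- 1000
#' granularity_spectrum(m, scales = 1:6)
#' @export
granularity_spectrum <- function(region_values, scales = 1:8, mask = NULL) {
  if (!is.matrix(region_values)) stop("region must be a 2-D raster")
  if (length(region_values) == 0L) stop("empty region")
  if (any(diff(scales) <= 0) || any(scales < 1)) {
    stop("scales must be strictly increasing radii >= 1")
  }
  x <- .as01(pmax(region_values, 0))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(x), ncol(x))
  total <- sum(x[mask])
  if (total <= 0) return(setNames(numeric(length(scales)),
                                  paste0("s", scales)))
  series <- .opening_series(x, scales)
  prev <- x
  out <- numeric(length(scales))
  for (i in seq_along(scales)) {
    out[i] <- 100 * sum((prev - series[[i]])[mask]) / total
    prev <- series[[i]]
  }
  setNames(pmax(out, 0), paste0("s", scales))
}
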