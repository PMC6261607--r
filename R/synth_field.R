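#' Default phenotype rendering parameters
#'
#' Parameters of the two rendered cell classes.  Myofibroblasts are larger,
#' express ~3x more alpha-smooth-muscle actin (alpha-SMA) organized into
#' oriented stress fibers (the granularity/texture contrast the classifier
#' exploits), and deposit more fibronectin (FN) with punctate fibrils;
#' fibroblasts show diffuse low-level staining.  Intensities are arbitrary
#' 16-bit counts.
#'
#' @param asma_factor mean alpha-SMA intensity ratio myofibroblast :
#'   fibroblast (default 3, matching the ~3-fold protein induction).
#' @return Nested parameter list used by [simulate_cell_field()].
#' @export
phenotype_params <- function(asma_factor = 3) {
  fib_asma <- 2500
  list(
    fibroblast = list(
      class = "fibroblast", major_axis = 8, axis_sd = 0.12,
      ecc_range = c(0.4, 0.8), asma_mean = fib_asma, fiber_count = 0,
      fiber_width = 1, fn_mean = 2000, fibril_density = 0, noise_cv = 0.15
    ),
    myofibroblast = list(
      class = "myofibroblast", major_axis = 12, axis_sd = 0.12,
      ecc_range = c(0.5, 0.9), asma_mean = fib_asma * asma_factor,
      fiber_count = 6, fiber_width = 1, fn_mean = 5000,
      fibril_density = 0.03, noise_cv = 0.15
    ),
    nucleus_radius = 3.8, dapi_mean = 15000, wholecell_mean = 5000,
    background = 300, shot_gain = 4, read_noise_sd = 30,
    min_center_dist = 16
  )
}

.check_phenotype_params <- function(params) {
  fb <- params$fibroblast; mf <- params$myofibroblast
  stopifnot(mf$asma_mean > fb$asma_mean,
            fb$asma_mean >= 0, mf$asma_mean <= 65535,
            fb$noise_cv >= 0, mf$noise_cv >= 0)
  invisible(params)
}

#' Expected myofibroblast fraction of a well
#'
#' Logistic dose rule linking the TGF-beta1 dose to the differentiated
#' fraction, attenuated by the plated compound's true concentration
#' response, so image-based and protein-based ground truths are mutually
#' consistent:
#' `f = f_min + (f_max - f_min) * Hill(dose; ec50, h) * (1 - E(conc))`
#' with `E` the compound's fractional inhibition
#' ([compound_inhibition()]).
#'
#' @param tgf_dose TGF-beta1 dose (ng/ml).
#' @param compound one row of a [generate_compound_library()] registry (or
#'   a list with `true_ic50_nM`, `efficacy`), or NULL.
#' @param conc compound concentration (nM).
#' @param f_min,f_max fractions at zero and saturating dose (a starved
#'   culture is essentially pure fibroblast; saturating TGF-beta1 drives
#'   near-complete differentiation).
#' @param ec50 half-maximal TGF-beta1 dose (ng/ml), shared with the
#'   alpha-SMA protein induction default.
#' @param h Hill slope of the differentiation-fraction rule.
#' @return Myofibroblast fraction in `[f_min, f_max]`.
#' @export
differentiation_fraction <- function(tgf_dose, compound = NULL, conc = 0,
                                     f_min = 0.005, f_max = 0.995,
                                     ec50 = 0.07, h = 2) {
  inh <- if (is.null(compound)) 0 else
    compound_inhibition(conc, compound$true_ic50_nM, compound$efficacy)
  f_min + (f_max - f_min) * hill(tgf_dose, ec50, h) * (1 - inh)
}

## rejection-sample n cell centers with a minimum pairwise distance;
## the floor keeps nuclei disjoint so ground truth and rendered nucleus
## components stay in one-to-one correspondence
.place_centers <- function(n, dim, margin, min_dist) {
  cx <- cy <- numeric(n)
  d <- min_dist
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(400)) {
      x <- runif(1, margin, dim[2] - margin)
      y <- runif(1, margin, dim[1] - margin)
      if (i == 1L ||
          min((cx[seq_len(i - 1)] - x)^2 + (cy[seq_len(i - 1)] - y)^2) >= d^2) {
        cx[i] <- x; cy[i] <- y; placed <- TRUE; break
      }
      if (try %% 100 == 0 && d > 10) d <- d - 1  # crowded field: relax spacing
    }
    if (!placed) stop("could not place ", n, " cells in a ",
                      dim[1], "x", dim[2], " field")
  }
  cbind(x = cx, y = cy)
}

#' Render a synthetic multi-channel well image with ground truth
#'
#' Renders `n_cells` elliptical cells of two phenotypes into a 4-channel
#' 16-bit raster (channel order DAPI, alpha-SMA, FN, whole-cell).
#' Myofibroblasts carry oriented high-intensity stress-fiber segments in
#' the alpha-SMA channel and punctate fibrils in FN; each cell's in-mask
#' mean intensity is rescaled to its class mean times a per-cell lognormal
#' factor, so configured class contrasts are reproduced by direct
#' averaging over the ground-truth masks.  Gaussian shot noise (variance
#' proportional to intensity) plus constant read noise is added on top of
#' a flat background.
#'
#' Coordinates are 0-based, row-major, origin top-left; masks are label
#' rasters sharing the image shape.
#'
#' @param n_cells number of cells to render (>= 0).
#' @param frac_myo myofibroblast fraction; when NULL it is derived from
#'   `tgf_dose`/`compound`/`conc` via [differentiation_fraction()].
#' @param params [phenotype_params()] list.
#' @param dim image size `c(rows, cols)`; must fit the largest cell.
#' @param seed integer seed (bit-reproducible output).
#' @param well well id recorded in the ground truth.
#' @param tgf_dose,compound,conc well condition used when `frac_myo` is
#'   NULL.
#' @return list with `image` (rows x cols x 4 numeric array, integer
#'   counts in `[0, 65535]`), `truth` (data.frame `well`, `cell_id`, `x`,
#'   `y`, `class`), `cell_mask` and `nucleus_mask` (integer label
#'   matrices), `frac_myo`, `seed`.
#' @examples
#' f <- simulate_cell_field(12, frac_myo = 0.5, dim = c(128, 128), seed = 1)
#' table(f$truth$class)
#' @export
simulate_cell_field <- function(n_cells, frac_myo = NULL,
                                params = phenotype_params(),
                                dim = c(256, 256), seed = 1L, well = "W01",
                                tgf_dose = 5, compound = NULL, conc = 0) {
  if (n_cells < 0) stop("n_cells must be >= 0")
  .check_phenotype_params(params)
  if (is.null(frac_myo)) {
    frac_myo <- differentiation_fraction(tgf_dose, compound, conc)
  }
  margin <- ceiling(params$myofibroblast$major_axis * (1 + 3 * params$myofibroblast$axis_sd)) + 2
  if (any(dim < 2 * margin + 4)) stop("image smaller than the largest cell template")

  H <- dim[1]; W <- dim[2]
  ch <- array(0, c(H, W, 4))
  cell_mask <- matrix(0L, H, W)
  nuc_mask <- matrix(0L, H, W)

  empty_truth <- data.frame(well = character(), cell_id = integer(),
                            x = numeric(), y = numeric(), class = character(),
                            stringsAsFactors = FALSE)
  if (n_cells == 0L) {
    img <- ch; img[, , ] <- params$background
    return(list(image = round(img), truth = empty_truth,
                cell_mask = cell_mask, nucleus_mask = nuc_mask,
                frac_myo = frac_myo, seed = seed))
  }

  .with_seed(seed, {
    centers <- .place_centers(n_cells, dim, margin, params$min_center_dist)
    is_myo <- runif(n_cells) < frac_myo
    classes <- ifelse(is_myo, "myofibroblast", "fibroblast")

    for (i in seq_len(n_cells)) {
      p <- if (is_myo[i]) params$myofibroblast else params$fibroblast
      a <- max(4, p$major_axis * (1 + rnorm(1, 0, p$axis_sd)))
      ecc <- runif(1, p$ecc_range[1], p$ecc_range[2])
      b <- max(2.5, a * sqrt(1 - ecc^2))
      th <- runif(1, 0, pi)
      cxi <- centers[i, 1]; cyi <- centers[i, 2]

      r0 <- max(1L, floor(cyi - a)); r1 <- min(H, ceiling(cyi + a))
      c0 <- max(1L, floor(cxi - a)); c1 <- min(W, ceiling(cxi + a))
      rr <- r0:r1; cc <- c0:c1
      dy <- outer(rr - cyi, rep(1, length(cc)))
      dx <- outer(rep(1, length(rr)), cc - cxi)
      u <- (dx * cos(th) + dy * sin(th)) / a
      v <- (-dx * sin(th) + dy * cos(th)) / b
      inside <- (u^2 + v^2) <= 1

      sub_cell <- cell_mask[rr, cc]
      own <- inside & sub_cell == 0L     # first-come priority at contacts
      sub_cell[own] <- i
      cell_mask[rr, cc] <- sub_cell

      ## nucleus disc at the center
      rn <- params$nucleus_radius
      nin <- (dx^2 + dy^2) <= rn^2
      sub_nuc <- nuc_mask[rr, cc]
      sub_nuc[nin & own] <- i
      nuc_mask[rr, cc] <- sub_nuc

      ## alpha-SMA texture: diffuse body, plus stress fibers for myofibroblasts
      tex <- matrix(0, length(rr), length(cc))
      tex[own] <- 1
      if (p$fiber_count > 0) {
        for (f in seq_len(p$fiber_count)) {
          phi <- th + rnorm(1, 0, 0.15)
          off <- runif(1, -0.8, 0.8) * b
          ox <- -sin(phi) * off; oy <- cos(phi) * off
          tpar <- seq(-a, a, by = 0.4)
          fx <- cxi + ox + tpar * cos(phi)
          fy <- cyi + oy + tpar * sin(phi)
          fw <- p$fiber_width
          for (k in seq_along(tpar)) {
            ri <- round(fy[k]) + (-fw:fw); ci <- round(fx[k]) + (-fw:fw)
            keep <- ri >= r0 & ri <= r1
            ri <- ri[keep]
            keep <- ci >= c0 & ci <= c1
            ci <- ci[keep]
            if (length(ri) && length(ci)) {
              loc <- as.matrix(expand.grid(ri - r0 + 1L, ci - c0 + 1L))
              sel <- loc[own[loc], , drop = FALSE]
              if (nrow(sel)) tex[sel] <- tex[sel] + 3
            }
          }
        }
      }
      if (p$fibril_density > 0) {
        idx <- which(own)
        k <- rbinom(1, length(idx), p$fibril_density)
        fn_tex <- matrix(0, length(rr), length(cc))
        fn_tex[own] <- 1
        if (k > 0) fn_tex[sample(idx, k)] <- 4
      } else {
        fn_tex <- matrix(0, length(rr), length(cc)); fn_tex[own] <- 1
      }

      scale_to <- function(tmat, target_mean) {
        m <- mean(tmat[own])
        if (m <= 0) return(tmat)
        tmat * (target_mean / m)
      }
      jit <- function(cv) rlnorm(1, -cv^2 / 2, cv)

      asma <- scale_to(tex, p$asma_mean * jit(p$noise_cv))
      fn <- scale_to(fn_tex, p$fn_mean * jit(p$noise_cv))
      wc <- matrix(0, length(rr), length(cc))
      wc[own] <- params$wholecell_mean * jit(p$noise_cv)
      dapi <- matrix(0, length(rr), length(cc))
      dapi[nin & own] <- params$dapi_mean * jit(p$noise_cv)

      ch[rr, cc, 1] <- ch[rr, cc, 1] + dapi
      ch[rr, cc, 2] <- ch[rr, cc, 2] + asma * own
      ch[rr, cc, 3] <- ch[rr, cc, 3] + fn * own
      ch[rr, cc, 4] <- ch[rr, cc, 4] + wc
    }

    ## flat background + shot noise (variance ~ intensity) + read noise
    for (k in 1:4) {
      I <- ch[, , k] + params$background
      noise <- rnorm(length(I), 0,
                     sqrt(params$shot_gain * pmax(I, 0) +
                            params$read_noise_sd^2))
      ch[, , k] <- .clamp(round(I + noise), 0, 65535)
    }

    truth <- data.frame(
      well = well, cell_id = seq_len(n_cells),
      x = centers[, 1] - 1, y = centers[, 2] - 1,  # 0-based, origin top-left
      class = classes, stringsAsFactors = FALSE
    )
    list(image = ch, truth = truth, cell_mask = cell_mask,
         nucleus_mask = nuc_mask, frac_myo = frac_myo, seed = seed)
  })
}

#' Write / read a synthetic field as multi-page 16-bit TIFF
#'
#' One page per channel, order DAPI, alpha-SMA, FN, whole-cell.
#'
#' @param field a [simulate_cell_field()] result (or a rows x cols x 4
#'   array of 16-bit counts).
#' @param path output TIFF path.
#' @return `write_field_tiff` invisibly returns `path`;
#'   `read_field_tiff` a rows x cols x 4 array of counts.
#' @export
write_field_tiff <- function(field, path) {
  img <- if (is.list(field)) field$image else field
  EBImage::writeImage(EBImage::Image(aperm(img, c(2, 1, 3)) / 65535),
                      path, type = "tiff", bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  x <- EBImage::readImage(path)
  round(aperm(EBImage::imageData(x), c(2, 1, 3)) * 65535)
}
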