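#' Otsu threshold of an intensity histogram
#'
#' Returns the bin value maximizing the between-class variance
#' \eqn{\sigma^2_B(t) = \omega_0 \omega_1 (\mu_0 - \mu_1)^2} of the two-class
#' split (bins \code{<= t} vs \code{> t}). Deterministic; among ties the
#' lowest maximizing bin value is returned.
#'
#' @param counts Non-negative bin counts.
#' @param values Bin values (ascending, same length as \code{counts});
#'   defaults to \code{0:(length(counts)-1)}.
#' @return The threshold: intensities \code{<= threshold} form the dark
#'   class, \code{> threshold} the bright class.
#' @export
otsu_threshold <- function(counts, values = seq_along(counts) - 1) {
  stopifnot(length(counts) == length(values), all(counts >= 0),
            !is.unsorted(values))
  nz <- counts > 0
  if (sum(nz) < 2L)
    stop("histogram needs at least 2 nonempty bins (single-valued image?)")
  w <- cumsum(counts)
  m <- cumsum(counts * values)
  n <- w[length(w)]
  mt <- m[length(m)]
  k <- seq_len(length(counts) - 1L)          # split after bin k
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, length(k))
  mu0 <- m[k][valid] / w0[valid]
  mu1 <- (mt - m[k][valid]) / w1[valid]
  sb[valid] <- (w0[valid] / n) * (w1[valid] / n) * (mu0 - mu1)^2
  values[which.max(sb)]                      # which.max: first (lowest) maximizer
}

# 256-bin histogram of a numeric matrix/vector over its own range.
intensity_histogram <- function(x, nbins = 256L) {
  r <- range(x, finite = TRUE)
  if (r[1] == r[2])
    stop("single-valued image: no separable classes")
  edges <- seq(r[1], r[2], length.out = nbins + 1L)
  counts <- tabulate(pmin(nbins, findInterval(x, edges, left.open = FALSE)),
                     nbins)
  list(counts = counts, values = (edges[-1] + edges[-length(edges)]) / 2)
}

# padded bounding box (row/col ranges) around the bright class: restricting
# threshold estimation to it keeps the huge dark background from dominating
# the class statistics
eye_roi <- function(bright_any, pad = 30L) {
  idx <- which(bright_any, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(list(rows = seq_len(nrow(bright_any)), cols = seq_len(ncol(bright_any))))
  list(rows = max(1L, min(idx[, 1]) - pad):min(nrow(bright_any), max(idx[, 1]) + pad),
       cols = max(1L, min(idx[, 2]) - pad):min(ncol(bright_any), max(idx[, 2]) + pad))
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) return(mask & FALSE)
  tab <- tabulate(lab[lab > 0])
  lab == which.max(tab)
}

# components of `mask` that do not touch the image border
interior_components <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab == 0) return(list(mask = mask & FALSE, n = 0L))
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  keep <- setdiff(seq_len(nlab), border)
  list(mask = matrix(lab %in% keep, nrow(lab), ncol(lab)), n = length(keep))
}

#' Segment one slice into vitreous cavity and gas
#'
#' Reproduces threshold-based planimetry of a T2-like slice: an Otsu
#' threshold separates the bright intraocular fluid from everything dark;
#' a second Otsu threshold within the dark class separates the very dark
#' gas/air from the intermediate sclera, so the scleral rim isolates the
#' intraocular gas from the background air. The gas is taken as the very-dark
#' connected component(s) enclosed by the globe (not touching the image
#' border); the cavity is the fluid component united with the gas, with the
#' thin partial-volume band at the meniscus closed morphologically.
#'
#' If the slice holds no fluid (pure gas fill), the bright class degenerates
#' to the scleral rim; this is detected (the "bright" component encloses the
#' gas) and the cavity is then the gas region alone.
#'
#' @param image Numeric matrix (one slice).
#' @param threshold Fluid/dark Otsu threshold; computed from the slice when
#'   \code{NULL}.
#' @param pixel_spacing_mm Pixel size, mm.
#' @param expect_gas If \code{TRUE} and no enclosed dark component is found,
#'   the result is flagged.
#' @return A list: logical \code{cavity} and \code{gas} masks,
#'   \code{threshold} (fluid), \code{threshold_dark} (gas vs sclera),
#'   \code{cavity_mm2}, \code{gas_mm2}, \code{n_gas_components},
#'   \code{flagged}.
#' @export
segment_slice <- function(image, threshold = NULL, pixel_spacing_mm,
                          expect_gas = FALSE, threshold_dark = NULL) {
  if (is.null(threshold)) {
    h <- intensity_histogram(image)
    t0 <- otsu_threshold(h$counts, h$values)
    roi <- eye_roi(image > t0)
    h <- intensity_histogram(image[roi$rows, roi$cols])
    threshold <- otsu_threshold(h$counts, h$values)
    if (is.null(threshold_dark)) {
      dk <- image[roi$rows, roi$cols]
      dk <- dk[dk <= threshold]
      if (length(dk) > 1 && diff(range(dk)) > 0) {
        hd <- intensity_histogram(dk)
        if (sum(hd$counts > 0) >= 2L)
          threshold_dark <- otsu_threshold(hd$counts, hd$values)
      }
    }
  }
  bright <- image > threshold
  flagged <- FALSE

  # seed gas region: very dark (below the gas/sclera Otsu threshold of the
  # dark class) and enclosed by the globe. The gas/sclera boundary midpoint
  # sits near t2, so this mask is unbiased along the eye wall but erodes at
  # the gas/fluid meniscus, whose boundary midpoint sits near t1; the seed is
  # therefore regrown below t1 inside the cavity afterwards.
  t2 <- threshold_dark
  if (is.null(t2)) {
    t2 <- NA_real_
    dark_px <- image[!bright]
    if (length(dark_px) > 1 && diff(range(dark_px)) > 0) {
      hd <- intensity_histogram(dark_px)
      if (sum(hd$counts > 0) >= 2L) t2 <- otsu_threshold(hd$counts, hd$values)
    }
  }
  seed <- image & FALSE
  {
    if (is.finite(t2)) {
      vd <- !bright & image <= t2
      # opening removes noise speckle and severs one-pixel leaks through the
      # scleral shell before the enclosure test
      vd <- EBImage::opening(vd, EBImage::makeBrush(3, "box")) > 0
      seed <- interior_components(vd)$mask
    }
  }

  fluid <- largest_component(bright)
  ring_like <- FALSE
  if (any(seed)) {
    hull <- EBImage::fillHull(fluid) > 0
    ring_like <- sum(hull & seed) > 0.9 * sum(seed) && sum(fluid) < 0.8 * sum(hull)
  }
  gas <- image & FALSE
  n_gas <- 0L
  if (ring_like) {
    cavity <- seed
    gas <- seed
    n_gas <- 1L
  } else if (any(fluid) || any(seed)) {
    cavity <- fluid | seed
    brush <- EBImage::makeBrush(7, "disc")
    cavity <- EBImage::fillHull(EBImage::closing(cavity, brush)) > 0
    if (any(seed)) {
      # regrow: every sub-t1 cavity pixel whose component touches the seed
      lab <- EBImage::bwlabel(cavity & image <= threshold)
      keep <- setdiff(unique(lab[seed]), 0L)
      n_gas <- length(keep)
      gas <- matrix(lab %in% keep, nrow(lab), ncol(lab))
      if (n_gas > 1L)
        warning("gas region split into ", n_gas,
                " components; keeping all enclosed dark components")
    }
  } else {
    cavity <- image & FALSE
  }
  if (expect_gas && !any(gas)) flagged <- TRUE

  pv <- refine_areas(image, cavity, gas, fluid)
  if (ring_like) {
    # the whole cavity is gas; both areas come from the same refinement
    pv$gas_px <- pv$cavity_px
    pv$gas_frac <- pv$cavity_frac
  }

  list(cavity = cavity, gas = gas,
       gas_frac = pv$gas_frac, cavity_frac = pv$cavity_frac,
       threshold = threshold, threshold_dark = t2,
       cavity_mm2 = pv$cavity_px * pixel_spacing_mm^2,
       gas_mm2 = pv$gas_px * pixel_spacing_mm^2,
       n_gas_components = n_gas, flagged = flagged)
}

# Partial-volume refinement of the cavity and gas areas. A binary pixel
# count is biased by up to half a pixel at every boundary, and because the
# meniscus chord sits at the same image rows in every slice of a stack that
# error accumulates coherently. Pixels in a one-pixel band around the gas
# boundary and around the cavity outer boundary are instead weighted by
# their apparent membership, linearly unmixing their intensity between the
# mean intensities of the two adjacent pure classes (gas/fluid at the
# meniscus, gas/sclera or fluid/sclera at the eye wall).
refine_areas <- function(image, cavity, gas, fluid) {
  out <- list(cavity_px = sum(cavity), gas_px = sum(gas),
              gas_frac = gas + 0, cavity_frac = cavity + 0)
  if (!any(cavity)) return(out)
  box <- EBImage::makeBrush(3, "box")
  box5 <- EBImage::makeBrush(5, "box")
  dil <- function(m) EBImage::dilate(m, box) > 0
  dil5 <- function(m) EBImage::dilate(m, box5) > 0
  ero <- function(m) EBImage::erode(m, box) > 0
  near_gas <- dil(gas)
  near_fluid <- dil(fluid)
  out_ring <- dil(cavity) & !cavity
  mu_g <- if (any(gas & !near_fluid & ero(gas))) mean(image[gas & !near_fluid & ero(gas)]) else NA
  core_fluid <- fluid & !near_gas & ero(fluid)
  mu_f <- if (any(core_fluid)) mean(image[core_fluid]) else NA
  wall <- dil(out_ring) & !cavity & !out_ring      # 2nd ring out: scleral shell
  # the thin scleral shell is partial-volume diluted from both sides, so its
  # plateau intensity is estimated as an upper quantile, not the mean
  mu_s <- if (any(wall)) stats::quantile(image[wall], 0.75, names = FALSE) else NA
  unmix <- function(i, mu_in, mu_out)
    pmin(1, pmax(0, (image[i] - mu_out) / (mu_in - mu_out)))

  # cavity: core counts 1, boundary rings unmixed between the sclera plateau
  # and a local interior-partner intensity (pure fluid, pure gas, or their
  # blend at the meniscus-wall junction)
  bandc <- (cavity & !ero(cavity)) | (dil5(cavity) & !cavity)
  if (!is.na(mu_s)) {
    kernc <- matrix(1, 9, 9)
    core <- (cavity & !bandc) + 0
    denc <- as.matrix(EBImage::filter2(core, kernc, boundary = 0))
    numc <- as.matrix(EBImage::filter2(core * image, kernc, boundary = 0))
    mu_in <- ifelse(denc > 1e-6, numc / pmax(denc, 1e-6), mu_s)
    d <- mu_in[bandc] - mu_s
    w <- pmin(1, pmax(0, (image[bandc] - mu_s) / ifelse(abs(d) > 1, d, 1)))
    w[abs(d) <= 1] <- 0
    out$cavity_px <- sum(cavity & !bandc) + sum(w)
    cfrac <- cavity + 0
    cfrac[bandc] <- w
    out$cavity_frac <- cfrac
  }
  # gas: core counts 1, meniscus band unmixed against fluid, wall band
  # against sclera
  if (any(gas) && !is.na(mu_g)) {
    bandg <- (gas & !ero(gas)) | (dil5(gas) & !gas)
    # the non-gas partner intensity is estimated per pixel from its own
    # neighbourhood (fluid at the meniscus, sclera at the wall, their blend
    # at the meniscus-wall junction)
    kern <- matrix(1, 9, 9)
    outside <- (!(EBImage::dilate(gas, EBImage::makeBrush(5, "box")) > 0)) + 0
    den <- as.matrix(EBImage::filter2(outside, kern, boundary = 0))
    num <- as.matrix(EBImage::filter2(outside * image, kern, boundary = 0))
    mu_other <- ifelse(den > 1e-6, num / pmax(den, 1e-6), mu_g)
    # the neighbourhood mean is dragged toward the dark background where the
    # scleral shell is thin; the partner tissue can never be darker than the
    # scleral plateau itself
    partner <- mu_other[bandg]
    if (!is.na(mu_s)) partner <- pmax(partner, mu_s)
    w <- pmin(1, pmax(0, (partner - image[bandg]) / pmax(partner - mu_g, 1)))
    w[partner - mu_g <= 1] <- 0
    out$gas_px <- sum(gas & !bandg) + sum(w)
    frac <- gas + 0
    frac[bandg] <- w
    out$gas_frac <- frac
  }
  # the gas is part of the cavity: the coverage maps must respect it even
  # where the cavity band's local interior estimate is undefined
  out$cavity_frac <- pmax(out$cavity_frac, out$gas_frac)
  out$gas_px <- min(out$gas_px, out$cavity_px)
  out
}

#' Gas volume as a percentage of the vitreous cavity
#'
#' Slice areas are integrated with the slice spacing (ratio of summed
#' volumes, which for uniform spacing equals the ratio of summed areas) and
#' the gas fraction expressed in percent.
#'
#' @param cavity_mm2,gas_mm2 Per-slice areas, mm^2.
#' @param slice_spacing_mm Scalar or per-slice spacing, mm.
#' @return Gas volume percent in \code{[0, 100]}.
#' @export
gas_volume_percent <- function(cavity_mm2, gas_mm2, slice_spacing_mm = 1) {
  stopifnot(length(cavity_mm2) == length(gas_mm2), length(cavity_mm2) >= 1)
  w <- rep_len(slice_spacing_mm, length(cavity_mm2))
  denom <- sum(cavity_mm2 * w)
  if (denom <= 0) stop("zero total cavity area")
  100 * sum(gas_mm2 * w) / denom
}

#' Segment a whole image stack
#'
#' Runs [segment_slice()] on every slice and integrates the per-slice areas
#' to the stack-level gas-volume percentage.
#'
#' @param stack An \code{image_stack}.
#' @return An object of class \code{"segmentation_result"}: \code{per_slice}
#'   data frame (slice, threshold, cavity_mm2, gas_mm2, flagged),
#'   \code{masks} (per-slice cavity/gas), \code{gas_volume_pct}.
#' @export
segment_stack <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  # thresholds from the pooled stack histogram, restricted to a padded box
  # around the bright class: a single slice can hold almost no fluid (the
  # outermost slices of a large bubble), where a per-slice Otsu split would
  # degenerate, and the full field of view is dominated by background air
  allpx <- unlist(stack$slices, use.names = FALSE)
  h <- intensity_histogram(allpx)
  t0 <- otsu_threshold(h$counts, h$values)
  bright_any <- Reduce(`|`, lapply(stack$slices, function(m) m > t0))
  roi <- eye_roi(bright_any)
  roipx <- unlist(lapply(stack$slices, function(m) m[roi$rows, roi$cols]),
                  use.names = FALSE)
  h <- intensity_histogram(roipx)
  t1 <- otsu_threshold(h$counts, h$values)
  dark_px <- roipx[roipx <= t1]
  t2 <- NULL
  if (length(dark_px) > 1 && diff(range(dark_px)) > 0) {
    hd <- intensity_histogram(dark_px)
    if (sum(hd$counts > 0) >= 2L) t2 <- otsu_threshold(hd$counts, hd$values)
  }
  segs <- lapply(stack$slices, segment_slice, threshold = t1,
                 pixel_spacing_mm = stack$pixel_spacing_mm,
                 threshold_dark = t2)
  per_slice <- data.frame(
    slice = seq_along(segs),
    threshold = vapply(segs, `[[`, numeric(1), "threshold"),
    cavity_mm2 = vapply(segs, `[[`, numeric(1), "cavity_mm2"),
    gas_mm2 = vapply(segs, `[[`, numeric(1), "gas_mm2"),
    flagged = vapply(segs, `[[`, logical(1), "flagged"))
  keep <- per_slice$cavity_mm2 > 0
  pct <- gas_volume_percent(per_slice$cavity_mm2[keep],
                            per_slice$gas_mm2[keep],
                            stack$slice_spacing_mm)
  structure(list(per_slice = per_slice,
                 masks = lapply(segs, `[`, c("cavity", "gas", "gas_frac", "cavity_frac")),
                 gas_volume_pct = pct,
                 pixel_spacing_mm = stack$pixel_spacing_mm,
                 slice_spacing_mm = stack$slice_spacing_mm),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d slices, gas volume %.1f%% of cavity\n",
              nrow(x$per_slice), x$gas_volume_pct))
  invisible(x)
}
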