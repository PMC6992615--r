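#' Select the slice matching the biometric axial length
#'
#' The measured slice is the one whose anterior-to-posterior extent along the
#' pupillary axis is closest to the axial length from optical biometry (ties
#' resolve to the lower slice index).
#'
#' @param seg A \code{segmentation_result}.
#' @param axial_length_mm Target axial length, mm.
#' @param axis Unit 2-vector (u, w) of the pupillary axis in the slice plane.
#' @param tol_mm Maximal acceptable |extent - axial length|; exceeding it is
#'   an error.
#' @return The selected slice index, with the per-slice extents (mm) as
#'   attribute \code{"extents"}.
#' @export
select_slice <- function(seg, axial_length_mm, axis, tol_mm = 2) {
  stopifnot(inherits(seg, "segmentation_result"))
  dx <- seg$pixel_spacing_mm
  n_img <- nrow(seg$masks[[1]]$cavity)
  extents <- vapply(seg$masks, function(m) {
    idx <- which(m$cavity, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NA_real_)
    uw <- px_to_mm(idx[, c(2, 1), drop = FALSE], n_img, dx)
    p <- uw %*% axis
    diff(range(p)) + dx
  }, numeric(1))
  err <- abs(extents - axial_length_mm)
  if (all(!is.finite(err)) || min(err, na.rm = TRUE) > tol_mm)
    stop("no slice extent within ", tol_mm, " mm of the axial length")
  structure(which.min(err), extents = extents)
}

#' Geometry of one segmented slice
#'
#' Bundles the cavity contour (ordered polygon, mm coordinates), the eye
#' centre (cavity centroid), and the pupillary axis estimated from the
#' anterior-chamber-angle landmarks: the axis runs from the centroid through
#' the midpoint of the two angle points. The superior direction is the
#' in-plane perpendicular pointing toward head-superior (\code{+u} columns).
#'
#' @param cavity,gas Logical masks of one slice.
#' @param pixel_spacing_mm Pixel size, mm.
#' @param angle_superior_px,angle_inferior_px Anterior-chamber-angle
#'   landmarks, continuous (col, row) pixels (e.g. from the phantom sidecar).
#' @return An object of class \code{"slice_geometry"}.
#' @export
slice_geometry <- function(cavity, gas, pixel_spacing_mm,
                           angle_superior_px, angle_inferior_px,
                           gas_frac = NULL, cavity_frac = NULL,
                           image = NULL) {
  stopifnot(is.matrix(cavity), is.matrix(gas))
  n_img <- nrow(cavity)
  dx <- pixel_spacing_mm
  if (!any(cavity)) stop("empty cavity mask")
  oc <- EBImage::ocontour(EBImage::bwlabel(largest_component(cavity)))[[1]]
  contour <- px_to_mm(cbind(oc[, 2] + 1, oc[, 1] + 1), n_img, dx)
  # centre from an algebraic least-squares circle fit to the contour: unlike
  # the mask centroid it is insensitive to the slight one-sided dilation of
  # the segmented cavity along the bright fluid arc
  centre <- fit_circle(contour)$centre
  ang_s <- drop(px_to_mm(rbind(angle_superior_px), n_img, dx))
  ang_i <- drop(px_to_mm(rbind(angle_inferior_px), n_img, dx))
  axis_pt <- (ang_s + ang_i) / 2
  a <- axis_pt - centre
  na <- sqrt(sum(a^2))
  if (na < 1e-9) stop("pupillary axis undefined: angle midpoint at centroid")
  a <- a / na
  s <- c(a[2], -a[1])
  if (s[1] < 0) s <- -s                  # superior = toward +u
  geom <- structure(list(contour_mm = contour, centre_mm = centre,
                         anterior = a, superior = s,
                         angle_superior_mm = ang_s, angle_inferior_mm = ang_i,
                         cavity = cavity, gas = gas,
                         gas_frac = if (is.null(gas_frac)) gas + 0 else gas_frac,
                         cavity_frac = if (is.null(cavity_frac)) cavity + 0 else cavity_frac,
                         image = image,
                         pixel_spacing_mm = dx, n_px = n_img),
                    class = "slice_geometry")
  if (!is.null(image)) {
    # second pass: refit the centre on the sub-pixel refined contour; the
    # raw traced boundary is dilated along the bright fluid arc, which would
    # bias the fitted centre toward gravity
    par <- contour_param(geom)
    pts <- cbind(par$centre[1] + par$r * (cos(par$phi) * geom$anterior[1] +
                                            sin(par$phi) * geom$superior[1]),
                 par$centre[2] + par$r * (cos(par$phi) * geom$anterior[2] +
                                            sin(par$phi) * geom$superior[2]))
    centre <- fit_circle(pts)$centre
    a <- axis_pt - centre
    a <- a / sqrt(sum(a^2))
    s <- c(a[2], -a[1])
    if (s[1] < 0) s <- -s
    geom$centre_mm <- centre
    geom$anterior <- a
    geom$superior <- s
  }
  geom
}

#' @export
print.slice_geometry <- function(x, ...) {
  cat(sprintf("<slice_geometry> %d contour vertices, centre (%.1f, %.1f) mm, axis (%.3f, %.3f)\n",
              nrow(x$contour_mm), x$centre_mm[1], x$centre_mm[2],
              x$anterior[1], x$anterior[2]))
  invisible(x)
}

# Algebraic (Kasa) least-squares circle fit; returns centre and radius.
fit_circle <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  a <- cbind(2 * x, 2 * y, 1)
  th <- qr.solve(a, x^2 + y^2)
  list(centre = c(th[1], th[2]),
       radius = sqrt(max(0, th[3] + th[1]^2 + th[2]^2)))
}

# Star-shaped parameterization of the contour about the fitted centre:
# phi = atan2(s-projection, a-projection) in (-pi, pi], phi = 0 at the
# anterior pole, positive on the superior side. When the geometry carries
# the slice image, the radius at each angle is refined to sub-pixel
# precision: the wall boundary is where the radial intensity profile
# crosses halfway between the local interior tissue value (fluid, gas, or
# their blend near the meniscus) and the scleral plateau. Otherwise the
# traced boundary pixels are used (their centres sit about half a pixel
# inside the true edge, which is compensated).
contour_param <- function(geom, smooth_mm = 0.5, n_grid = 1440L) {
  rel <- sweep(geom$contour_mm, 2, geom$centre_mm)
  pa <- drop(rel %*% geom$anterior)
  ps <- drop(rel %*% geom$superior)
  phi0 <- atan2(ps, pa)
  r0 <- sqrt(pa^2 + ps^2)
  o <- order(phi0)
  phi0 <- phi0[o]; r0 <- r0[o]
  # light circular smoothing of the radius suppresses pixel staircase jitter
  if (smooth_mm > 0 && length(r0) > 8) {
    k <- max(3L, 2L * floor(smooth_mm / (mean(r0) * mean(diff(phi0))) / 2) + 1L)
    k <- min(k, 2L * floor((length(r0) - 1) / 2) + 1L)
    half <- (k - 1L) %/% 2L
    rpad <- c(utils::tail(r0, half), r0, utils::head(r0, half))
    r0 <- stats::filter(rpad, rep(1 / k, k), sides = 2)[(half + 1):(half + length(phi0))]
  }
  dx <- geom$pixel_spacing_mm
  phi <- seq(-pi, pi, length.out = n_grid + 1L)[-1]
  r <- stats::approx(c(phi0[length(phi0)] - 2 * pi, phi0, phi0[1] + 2 * pi),
                     c(r0[length(r0)], r0, r0[1]), xout = phi)$y
  img <- geom$image
  if (!is.null(img)) {
    dir_u <- cos(phi) * geom$anterior[1] + sin(phi) * geom$superior[1]
    dir_w <- cos(phi) * geom$anterior[2] + sin(phi) * geom$superior[2]
    sample_at <- function(rr) {
      uw <- cbind(geom$centre_mm[1] + rr * dir_u,
                  geom$centre_mm[2] + rr * dir_w)
      cr <- mm_to_px(uw, geom$n_px, dx)
      bilinear_mask(img, cr[, 2], cr[, 1])
    }
    # reference intensities: interior tissue 2 px inside the traced wall,
    # scleral plateau as an upper quantile of a ring outside it (the thin
    # shell is partial-volume diluted from both sides)
    i_in <- sample_at(r - 2 * dx)
    mu_s <- stats::quantile(c(sample_at(r + 2 * dx), sample_at(r + 2.5 * dx)),
                            0.75, names = FALSE)
    steps <- seq(-1.5, 1.5, by = 0.25) * dx
    prof <- sapply(steps, function(dr) sample_at(r + dr))
    # normalised departure from the interior value toward the sclera; where
    # the interior blend is indistinguishable from the sclera (a gas/fluid
    # mixture near the meniscus-wall junction can land on the plateau value)
    # the criterion is degenerate and the traced radius is kept
    gmat <- abs(prof - i_in) / pmax(abs(mu_s - i_in), 10)
    usable <- abs(mu_s - i_in) >= 15
    refined <- r + dx / 2
    for (j in seq_along(phi)) {
      if (!usable[j]) next
      v <- gmat[j, ]
      idx <- which(v[-length(v)] < 0.5 & v[-1] >= 0.5)
      if (length(idx)) {
        i <- min(idx)                       # first outward half-crossing
        frac <- (0.5 - v[i]) / max(v[i + 1] - v[i], 1e-9)
        refined[j] <- r[j] + steps[i] + frac * (steps[i + 1] - steps[i])
      }
    }
    r <- refined
    # circular running median kills localised spikes, then stretches that
    # still deviate from a robust circle fit are repaired by the fitted
    # circle: at the meniscus-wall junction the image is a featureless
    # partial-volume blend in which no local wall crossing exists, and the
    # globe is spherical by model assumption
    hm <- 15L
    rpad <- c(utils::tail(r, hm), r, utils::head(r, hm))
    r <- stats::runmed(rpad, 2L * hm + 1L)[(hm + 1):(hm + length(phi))]
    px <- geom$centre_mm[1] + r * dir_u
    py <- geom$centre_mm[2] + r * dir_w
    keep <- rep(TRUE, length(phi))
    for (it in 1:3) {
      fit <- fit_circle(cbind(px[keep], py[keep]))
      resid <- sqrt((px - fit$centre[1])^2 + (py - fit$centre[2])^2) - fit$radius
      keep <- abs(resid) < 0.15
      if (all(keep)) break
    }
    if (any(!keep)) {
      # ray-circle intersection about the parameterisation centre
      ocx <- geom$centre_mm[1] - fit$centre[1]
      ocy <- geom$centre_mm[2] - fit$centre[2]
      b <- ocx * dir_u[!keep] + ocy * dir_w[!keep]
      cc <- ocx^2 + ocy^2 - fit$radius^2
      disc <- pmax(0, b^2 - cc)
      r[!keep] <- -b + sqrt(disc)
    }
    k <- 11L; half <- 5L
    rpad <- c(utils::tail(r, half), r, utils::head(r, half))
    r <- stats::filter(rpad, rep(1 / k, k), sides = 2)[(half + 1):(half + length(phi))]
  } else {
    r <- r + dx / 2
  }
  # arc length accumulated over the phi-sorted polygon (closed)
  x <- r * cos(phi); y <- r * sin(phi)
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  list(phi = phi, r = r, arc = c(0, cumsum(seg)),
       closing_seg = sqrt((x[1] - x[length(x)])^2 + (y[1] - y[length(y)])^2),
       centre = geom$centre_mm, anterior = geom$anterior,
       superior = geom$superior)
}

# bilinear sample of a logical matrix at continuous (row, col) positions
bilinear_mask <- function(mask, r, c) {
  nr <- nrow(mask); nc <- ncol(mask)
  r <- pmin(nr - 1e-9, pmax(1, r)); c <- pmin(nc - 1e-9, pmax(1, c))
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r1 <- pmin(nr, r0 + 1); c1 <- pmin(nc, c0 + 1)
  mask[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    mask[cbind(r1, c0)] * fr * (1 - fc) +
    mask[cbind(r0, c1)] * (1 - fr) * fc +
    mask[cbind(r1, c1)] * fr * fc
}

# interpolated radius and point (world mm) at angle phi
param_point <- function(par, phi) {
  r <- stats::approx(c(par$phi[length(par$phi)] - 2 * pi, par$phi,
                       par$phi[1] + 2 * pi),
                     c(par$r[length(par$r)], par$r, par$r[1]),
                     xout = phi, rule = 2)$y
  list(r = r,
       point = cbind(par$centre[1] + r * (cos(phi) * par$anterior[1] + sin(phi) * par$superior[1]),
                     par$centre[2] + r * (cos(phi) * par$anterior[2] + sin(phi) * par$superior[2])))
}

# arc length along the contour between two angles (phi1 < phi2, no wrap)
param_arclen <- function(par, phi1, phi2) {
  stopifnot(phi2 >= phi1)
  grid <- seq(phi1, phi2, length.out = max(8, ceiling((phi2 - phi1) / 0.005)))
  r <- param_point(par, grid)$r
  x <- r * cos(grid); y <- r * sin(grid)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

# walk from phi0 in direction dir (+1/-1) until `dist` mm of arc is
# accumulated; returns the angle reached. Errors at the posterior pole.
param_walk <- function(par, phi0, dir, dist) {
  f <- function(phi) param_arclen(par, min(phi0, phi), max(phi0, phi)) - dist
  hi <- if (dir > 0) pi else -pi
  if (f(hi) < 0)
    stop("contour shorter than ", dist, " mm from the start point")
  stats::uniroot(f, sort(c(phi0 + dir * 1e-9, hi)), tol = 1e-9)$root
}

#' Locate the surgical limbus on a slice
#'
#' From each anterior-chamber-angle landmark, the line perpendicular to the
#' pupillary axis is cast and its intersection with the outer contour on the
#' same (superior or inferior) side is the surgical limbus.
#'
#' @param geom A [slice_geometry()].
#' @return List with \code{superior} and \code{inferior} limbus points (mm)
#'   and their contour angles \code{phi}.
#' @export
locate_limbus <- function(geom) {
  par <- contour_param(geom)
  one <- function(angle_mm, side) {
    rel <- angle_mm - geom$centre_mm
    x0 <- sum(rel * geom$anterior)
    # solve r(phi) cos(phi) = x0 on the given side
    g <- function(phi) param_point(par, phi)$r * cos(phi) - x0
    lo <- if (side > 0) 1e-6 else -pi / 2
    hi <- if (side > 0) pi / 2 else -1e-6
    # widen until sign change (angle may sit anterior of +/- pi/2 only)
    if (g(lo) * g(hi) > 0) stop("no intersection: angle point outside the globe")
    phi <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
    pt <- param_point(par, phi)$point
    list(phi = phi, point = drop(pt))
  }
  rel_s <- sum((geom$angle_superior_mm - geom$centre_mm) * geom$superior)
  rel_i <- sum((geom$angle_inferior_mm - geom$centre_mm) * geom$superior)
  if (rel_s <= 0 || rel_i >= 0)
    stop("angle landmarks are not on opposite sides of the pupillary axis")
  list(superior = one(geom$angle_superior_mm, +1),
       inferior = one(geom$angle_inferior_mm, -1))
}

#' Place the ora serrata and equator landmarks
#'
#' Walks posteriorly along the contour from each limbus point and marks the
#' points at arc distance \code{ora_mm} (ora serrata) and \code{equator_mm}
#' (equator at the vortex-vein ampullae); distances are arc length along the
#' globe surface.
#'
#' @param geom A [slice_geometry()].
#' @param limbus Output of [locate_limbus()]; recomputed when \code{NULL}.
#' @param ora_mm,equator_mm Arc distances posterior to the limbus, mm.
#' @return Object of class \code{"slice_landmarks"}: per side, the contour
#'   angles and points of limbus, ora and equator.
#' @export
place_landmarks <- function(geom, limbus = NULL, ora_mm = 7, equator_mm = 13.5) {
  if (is.null(limbus)) limbus <- locate_limbus(geom)
  par <- contour_param(geom)
  side <- function(lb, dir) {
    phi_ora <- param_walk(par, lb$phi, dir, ora_mm)
    phi_eq <- param_walk(par, lb$phi, dir, equator_mm)
    list(limbus = lb,
         ora = list(phi = phi_ora, point = drop(param_point(par, phi_ora)$point)),
         equator = list(phi = phi_eq, point = drop(param_point(par, phi_eq)$point)))
  }
  structure(list(superior = side(limbus$superior, +1),
                 inferior = side(limbus$inferior, -1),
                 par = par),
            class = "slice_landmarks")
}

#' Four-part retinal partition of a measured slice
#'
#' Splits the retina at the pupillary axis (superior/inferior) and at the
#' equator (posterior: pole to equator; anterior: equator to ora serrata),
#' with part lengths measured along the traced contour in mm.
#'
#' @param geom A [slice_geometry()].
#' @param landmarks A [place_landmarks()] result; recomputed when
#'   \code{NULL}.
#' @return Data frame of class \code{"retinal_partition"} with
#'   \code{phi_start}, \code{phi_end} and measured \code{length_mm} per part.
#' @export
partition_retina <- function(geom, landmarks = NULL) {
  if (is.null(landmarks)) landmarks <- place_landmarks(geom)
  par <- landmarks$par
  sup <- landmarks$superior; inf <- landmarks$inferior
  if (!(sup$ora$phi < sup$equator$phi && sup$equator$phi < pi))
    stop("superior landmarks out of order along the contour")
  if (!(inf$ora$phi > inf$equator$phi && inf$equator$phi > -pi))
    stop("inferior landmarks out of order along the contour")
  parts <- data.frame(
    part = c("superior_posterior", "superior_anterior",
             "inferior_posterior", "inferior_anterior"),
    phi_start = c(sup$equator$phi, sup$ora$phi, -pi, inf$equator$phi),
    phi_end = c(pi, sup$equator$phi, inf$equator$phi, inf$ora$phi),
    stringsAsFactors = FALSE)
  parts$length_mm <- mapply(function(p1, p2) param_arclen(par, p1, p2),
                            parts$phi_start, parts$phi_end)
  if (any(parts$length_mm <= 0)) stop("degenerate (zero-length) retinal part")
  structure(parts, class = c("retinal_partition", "data.frame"), par = par)
}

#' Measure gas contact rates on a segmented slice
#'
#' An arc point is in contact with the gas if a gas pixel lies within
#' \code{tolerance_px} along the inward normal (a segmented fluid film
#' thinner than the pixel cannot be distinguished from true apposition).
#' Contact length is the arc measure of contacting points; the rate is
#' contact length / part length x 100.
#'
#' @param geom A [slice_geometry()].
#' @param partition A measured [partition_retina()] result.
#' @param tolerance_px Inward search depth in pixels.
#' @param step_mm Arc sampling step, mm.
#' @return Data frame of class \code{"contact_rates"}: per part, part length,
#'   contact length and rate (percent).
#' @export
measure_contact <- function(geom, partition = partition_retina(geom),
                            tolerance_px = 1, step_mm = 0.05,
                            coverage_level = 0.4) {
  par <- attr(partition, "par")
  gas <- geom$gas_frac
  cav <- geom$cavity_frac
  dx <- geom$pixel_spacing_mm
  n_img <- geom$n_px
  out <- partition
  out$contact_length_mm <- 0
  for (i in seq_len(nrow(partition))) {
    p1 <- partition$phi_start[i]; p2 <- partition$phi_end[i]
    m <- max(9, ceiling(partition$length_mm[i] / step_mm))
    grid <- seq(p1, p2, length.out = m)
    pp <- param_point(par, grid)
    pts <- pp$point
    nrm <- cbind(par$centre[1] - pts[, 1], par$centre[2] - pts[, 2])
    nrm <- nrm / sqrt(rowSums(nrm^2))
    hit <- rep(FALSE, m)
    # the march starts half a pixel outside the traced wall: the contour
    # itself is only sub-pixel accurate, and outside the globe both
    # coverage maps vanish so the outward samples cannot create contact
    for (t_px in seq(-0.5, tolerance_px, by = 0.25)) {
      q <- pts + nrm * (t_px * dx)
      cr <- mm_to_px(q, n_img, dx)
      # contact where the gas fraction OF THE LOCAL CAVITY CONTENT reaches
      # coverage_level: normalising by the fractional cavity map undoes the
      # dilution of wall cells that lie partly outside the globe
      bg <- bilinear_mask(gas, cr[, 2], cr[, 1])
      bc <- bilinear_mask(cav, cr[, 2], cr[, 1])
      hit <- hit | (bc >= 0.2 & bg / pmax(bc, 0.2) >= coverage_level)
    }
    # arc measure: trapezoid weights of the sampled polyline
    seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
    wts <- c(seg / 2, 0) + c(0, seg / 2)
    out$contact_length_mm[i] <- sum(wts[hit])
  }
  # numerical guard: the sampled contact measure can exceed the part length
  # by floating error when a part is fully covered
  out$contact_length_mm <- pmin(out$contact_length_mm, out$length_mm)
  out$rate_pct <- 100 * out$contact_length_mm / out$length_mm
  res <- data.frame(part = out$part,
                    part_length_mm = out$length_mm,
                    contact_length_mm = out$contact_length_mm,
                    rate_pct = out$rate_pct,
                    stringsAsFactors = FALSE)
  class(res) <- c("contact_rates", "data.frame")
  res
}

#' Supraduction angle of the eye on a slice
#'
#' Signed angle between the pupillary axis and the perpendicular (vertical)
#' line to the ground, positive toward head-superior (supraduction, as in
#' upward eye rotation under closed lids), negative for infraduction. The
#' vertical reference flips with posture: supine eyes face up, prone eyes
#' face down.
#'
#' @param geom A [slice_geometry()].
#' @param posture \code{"supine"} or \code{"prone"}.
#' @return Angle in degrees.
#' @export
measure_supraduction <- function(geom, posture = c("supine", "prone")) {
  posture <- match.arg(posture)
  a <- geom$anterior
  if (sqrt(sum(a^2)) < 1e-9) stop("pupillary axis undefined")
  ref <- if (posture == "supine") a[2] else -a[2]
  unname(atan2(a[1], ref)) * 180 / pi
}
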