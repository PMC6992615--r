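#' Spherical-cap height for a target gas fill fraction
#'
#' An intraocular gas bubble floats against gravity and is bounded below by a
#' flat meniscus, so inside a spherical vitreous cavity of radius \code{R} it
#' occupies a spherical cap. This solves the cap-volume cubic
#' \eqn{h^2 (3R - h) = 4 f R^3} for the cap height \eqn{h \in [0, 2R]} given
#' the fill fraction \eqn{f} (gas volume / cavity volume).
#'
#' The cubic is solved in closed (trigonometric) form, accurate to machine
#' precision; \code{fraction_from_cap_height()} is its exact inverse.
#'
#' @param f Fill fraction in \code{[0, 1]}.
#' @param R Cavity radius in mm, positive.
#' @return Cap height in mm, monotone increasing in \code{f}.
#' @seealso [fraction_from_cap_height()], [meniscus_plane()]
#' @export
#' @examples
#' cap_height_from_fraction(0.5, 12)  # hemisphere: h = R
cap_height_from_fraction <- function(f, R) {
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("fill fraction must be in [0, 1]")
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("cavity radius must be a single positive number")
  # h/R = 1 + 2*cos((acos(1 - 2f) + 4*pi)/3) solves (h/R)^3 - 3(h/R)^2 + 4f = 0
  g <- (acos(pmin(1, pmax(-1, 1 - 2 * f))) + 4 * pi) / 3
  h <- R * (1 + 2 * cos(g))
  pmin(2 * R, pmax(0, h))
}

#' Gas fill fraction from spherical-cap height
#'
#' Inverse of [cap_height_from_fraction()]:
#' \eqn{f = h^2 (3R - h) / (4 R^3)}.
#'
#' @param h Cap height in mm, in \code{[0, 2R]}.
#' @param R Cavity radius in mm, positive.
#' @return Fill fraction in \code{[0, 1]}.
#' @export
fraction_from_cap_height <- function(h, R) {
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("cavity radius must be a single positive number")
  if (!is.numeric(h) || any(!is.finite(h)) || any(h < 0) || any(h > 2 * R))
    stop("cap height must be in [0, 2R]")
  h^2 * (3 * R - h) / (4 * R^3)
}

#' Geometric model of one post-vitrectomy eye
#'
#' The vitreous cavity is modelled as a perfect sphere. By default its radius
#' is \code{(axial_length - anterior_offset) / 2}: the axial length measured
#' by optical biometry spans cornea to retina, and \code{anterior_offset}
#' (default 1.6 mm) absorbs the cornea/anterior-chamber depth that is not part
#' of the vitreous cavity in a pseudophakic, vitrectomised eye. The surgical
#' limbus sits at arc distance \code{limbus_offset_mm} from the corneal pole
#' along the globe surface.
#'
#' @param axial_length_mm Axial length in mm (cornea to retina).
#' @param radius_mm Cavity radius in mm; defaults to
#'   \code{(axial_length_mm - anterior_offset_mm) / 2}.
#' @param anterior_offset_mm Cornea + anterior chamber allowance in mm.
#' @param limbus_offset_mm Corneal pole to surgical limbus, arc mm.
#' @return An object of class \code{"eye_model"}.
#' @export
eye_model <- function(axial_length_mm, radius_mm = NULL,
                      anterior_offset_mm = 1.6, limbus_offset_mm = 6.0) {
  if (is.null(radius_mm)) radius_mm <- (axial_length_mm - anterior_offset_mm) / 2
  stopifnot(radius_mm > 0, axial_length_mm >= 2 * radius_mm, limbus_offset_mm > 0)
  structure(list(radius = radius_mm,
                 axial_length = axial_length_mm,
                 anterior_offset = anterior_offset_mm,
                 limbus_offset = limbus_offset_mm),
            class = "eye_model")
}

#' @export
print.eye_model <- function(x, ...) {
  cat(sprintf("<eye_model> cavity radius %.2f mm, axial length %.1f mm, limbus at %.1f mm arc\n",
              x$radius, x$axial_length, x$limbus_offset))
  invisible(x)
}

#' Gas bubble inside an eye
#'
#' Resolves a fill fraction to a spherical-cap height for the given eye.
#'
#' @param fill_fraction Gas volume as a fraction of cavity volume, in
#'   \code{[0, 1]}.
#' @param eye An [eye_model()].
#' @return An object of class \code{"gas_bubble"} with the derived
#'   \code{cap_height} (mm).
#' @export
gas_bubble <- function(fill_fraction, eye) {
  stopifnot(inherits(eye, "eye_model"))
  h <- cap_height_from_fraction(fill_fraction, eye$radius)
  structure(list(fill_fraction = fill_fraction, cap_height = h,
                 radius = eye$radius),
            class = "gas_bubble")
}

#' @export
print.gas_bubble <- function(x, ...) {
  cat(sprintf("<gas_bubble> fill %.1f%% of cavity, cap height %.2f mm (R = %.2f mm)\n",
              100 * x$fill_fraction, x$cap_height, x$radius))
  invisible(x)
}

# In-slice (sagittal) world frame: u = horizontal, toward head-superior;
# w = vertical, up (against gravity). Returns the eye's anterior and superior
# unit vectors for a posture and supraduction angle. Supraduction (positive
# angle between the pupillary axis and the vertical, measured toward
# head-superior) is positive in both postures; the vertical reference flips
# with posture (supine: anterior up; prone: anterior down).
eye_orientation <- function(posture = c("supine", "prone"), supraduction_deg = 0) {
  posture <- match.arg(posture)
  th <- supraduction_deg * pi / 180
  if (posture == "supine") {
    list(anterior = c(sin(th),  cos(th)), superior = c(cos(th), -sin(th)))
  } else {
    list(anterior = c(sin(th), -cos(th)), superior = c(cos(th),  sin(th)))
  }
}

# Angle of a retinal point in the eye frame: phi = 0 at the anterior
# (corneal) pole, positive toward the superior side, phi = +/-pi at the
# posterior pole.
eye_frame_angle <- function(xy, orientation) {
  atan2(xy %*% orientation$superior, xy %*% orientation$anterior)
}

#' Flat gas-fluid meniscus plane
#'
#' The meniscus is modelled as a flat plane perpendicular to gravity (the
#' large SF6 bubble dwarfs the capillary length, so interface curvature is
#' negligible). The gas cap lies on the anti-gravity side; the plane height is
#' set so the cap holds \code{fill_fraction} of the cavity volume.
#'
#' @param eye An [eye_model()].
#' @param bubble A [gas_bubble()].
#' @return A list: \code{normal} (unit 2-vector in the slice frame, pointing
#'   up, i.e. minus gravity), \code{offset_mm} (signed height of the plane
#'   above the eye centre; gas occupies \code{w >= offset_mm}).
#' @export
meniscus_plane <- function(eye, bubble) {
  stopifnot(inherits(eye, "eye_model"), inherits(bubble, "gas_bubble"))
  list(normal = c(0, 1), offset_mm = eye$radius - bubble$cap_height)
}

#' Four-part retinal partition on the mid-sagittal circle
#'
#' Places the surgical limbus, the ora serrata (7 mm posterior to the limbus,
#' arc length along the globe) and the equator (13.5 mm posterior to the
#' limbus) on each side of the pupillary axis, then splits the retina into
#' four arcs: superior-posterior and inferior-posterior run from the posterior
#' pole (intersection of the pupillary axis with the retina) to the equator;
#' superior-anterior and inferior-anterior run from the equator to the ora
#' serrata. Retina anterior to the ora is excluded.
#'
#' @param eye An [eye_model()].
#' @param ora_mm Arc distance limbus to ora serrata (mm).
#' @param equator_mm Arc distance limbus to equator (mm).
#' @return An object of class \code{"retinal_partition"}: a data frame with
#'   one row per part (\code{phi_start < phi_end}, eye-frame radians, and
#'   \code{length_mm}), plus landmark angles as attributes.
#' @export
retinal_partition <- function(eye, ora_mm = 7, equator_mm = 13.5) {
  stopifnot(inherits(eye, "eye_model"), equator_mm > ora_mm, ora_mm > 0)
  R <- eye$radius
  phi_limbus <- eye$limbus_offset / R
  phi_ora <- (eye$limbus_offset + ora_mm) / R
  phi_eq <- (eye$limbus_offset + equator_mm) / R
  if (phi_eq >= pi)
    stop("equator lands beyond the posterior pole: contour shorter than ",
         equator_mm, " mm from the limbus")
  parts <- data.frame(
    part = c("superior_posterior", "superior_anterior",
             "inferior_posterior", "inferior_anterior"),
    phi_start = c(phi_eq, phi_ora, -pi, -phi_eq),
    phi_end = c(pi, phi_eq, -phi_eq, -phi_ora),
    stringsAsFactors = FALSE)
  parts$length_mm <- (parts$phi_end - parts$phi_start) * R
  if (any(parts$length_mm <= 0)) stop("degenerate (zero-length) retinal part")
  structure(parts, class = c("retinal_partition", "data.frame"),
            landmarks = c(limbus = phi_limbus, ora = phi_ora, equator = phi_eq),
            radius = R)
}

# Length of the overlap, on the circle, between the arc [p, q] (p < q,
# q - p <= 2*pi) and the arc [lo, hi] (hi - lo <= 2*pi).
circular_overlap <- function(p, q, lo, hi) {
  tot <- 0
  for (k in -1:1) {
    tot <- tot + max(0, min(q, hi + 2 * pi * k) - max(p, lo + 2 * pi * k))
  }
  tot
}

#' Closed-form gas contact rates per retinal part
#'
#' For each retinal arc, the contact length is the arc measure of points on
#' the gas side of the meniscus plane (points exactly on the plane count as
#' contact; they have measure zero), and the contact rate is
#' contact length / part length x 100.
#'
#' In the slice frame the retinal point at eye-frame angle \eqn{\phi} has
#' height \eqn{w = \pm R\cos(\phi + \theta)} (sign by posture,
#' \eqn{\theta} = supraduction), so the gas-contact set is a single arc of
#' half-width \eqn{A = \arccos(1 - h/R)} centred on \eqn{-\theta} (supine) or
#' \eqn{\pi - \theta} (prone); rates are exact circular-arc overlaps.
#'
#' @param eye An [eye_model()].
#' @param bubble A [gas_bubble()].
#' @param posture \code{"supine"} or \code{"prone"}.
#' @param supraduction_deg Signed supraduction angle, degrees (positive =
#'   supraduction, negative = infraduction).
#' @param partition A [retinal_partition()]; defaults to the eye's own.
#' @return A data frame of class \code{"contact_rates"}: part, part_length_mm,
#'   contact_length_mm, rate_pct, posture.
#' @export
analytic_contact_rates <- function(eye, bubble,
                                   posture = c("supine", "prone"),
                                   supraduction_deg = 0,
                                   partition = retinal_partition(eye)) {
  posture <- match.arg(posture)
  stopifnot(inherits(eye, "eye_model"), inherits(bubble, "gas_bubble"))
  R <- eye$radius
  th <- supraduction_deg * pi / 180
  A <- acos(pmin(1, pmax(-1, 1 - bubble$cap_height / R)))
  centre <- if (posture == "supine") -th else pi - th
  contact <- vapply(seq_len(nrow(partition)), function(i) {
    circular_overlap(partition$phi_start[i], partition$phi_end[i],
                     centre - A, centre + A) * R
  }, numeric(1))
  out <- data.frame(part = partition$part,
                    part_length_mm = partition$length_mm,
                    contact_length_mm = contact,
                    rate_pct = 100 * contact / partition$length_mm,
                    posture = posture,
                    stringsAsFactors = FALSE)
  class(out) <- c("contact_rates", "data.frame")
  out
}
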