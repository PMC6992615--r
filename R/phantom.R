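#' Imaging parameters for the synthetic eye phantom
#'
#' Defaults emulate a sagittal T2-weighted fast-spin-echo orbital acquisition:
#' 140 mm field of view on a 320 x 320 matrix (0.4375 mm square pixels),
#' 3.0 mm slices with a 0.5 mm gap (3.5 mm slice spacing). Motion-robust
#' acquisition is emulated only as Gaussian blur; noise is additive Gaussian.
#'
#' @param fov_mm Field of view, mm.
#' @param matrix_size Image matrix (square), pixels.
#' @param slice_thickness_mm Slice thickness, mm.
#' @param slice_gap_mm Inter-slice gap, mm.
#' @param noise_sd Additive Gaussian noise SD, intensity units (0-255 scale).
#' @param blur_sigma_px Gaussian blur sigma, pixels.
#' @param seed Integer seed making the rendered stack reproducible.
#' @return A list of class \code{"imaging_params"}.
#' @export
imaging_params <- function(fov_mm = 140, matrix_size = 320,
                           slice_thickness_mm = 3.0, slice_gap_mm = 0.5,
                           noise_sd = 5, blur_sigma_px = 0.7, seed = 1L) {
  stopifnot(fov_mm > 0, matrix_size >= 16,
            slice_thickness_mm > 0, slice_gap_mm >= 0, noise_sd >= 0)
  structure(list(fov_mm = fov_mm, matrix_size = as.integer(matrix_size),
                 slice_thickness_mm = slice_thickness_mm,
                 slice_gap_mm = slice_gap_mm,
                 pixel_spacing_mm = fov_mm / matrix_size,
                 slice_spacing_mm = slice_thickness_mm + slice_gap_mm,
                 noise_sd = noise_sd, blur_sigma_px = blur_sigma_px,
                 seed = as.integer(seed)),
            class = "imaging_params")
}

# Tissue intensities (arbitrary T2-like units on a 0-255 scale):
# intraocular fluid bright, gas and air dark, sclera and anterior segment
# intermediate.
.intensity <- list(background = 20, gas = 20, fluid = 200, sclera = 60,
                   anterior = 60, iris = 20)

# mm <-> pixel converters. Image rows run top to bottom; world w runs up.
# World u (+ = head-superior) maps to increasing column.
mm_to_px <- function(uw, n, dx) {
  cbind(col = uw[, 1] / dx + (n + 1) / 2,
        row = (n + 1) / 2 - uw[, 2] / dx)
}
px_to_mm <- function(colrow, n, dx) {
  cbind(u = (colrow[, 1] - (n + 1) / 2) * dx,
        w = ((n + 1) / 2 - colrow[, 2]) * dx)
}

# 4x4 block mean pooling of an (ss*n) x (ss*n) matrix down to n x n.
block_mean <- function(m, ss) {
  n <- nrow(m) / ss
  dim(m) <- c(ss, n * n * ss)
  m <- matrix(colMeans(m), n, n * ss)    # rows pooled
  m <- t(m)                               # now (n*ss) x n
  dim(m) <- c(ss, n * n)
  t(matrix(colMeans(m), n, n))            # cols pooled, back to row-major
}

# Area (mm^2) of the part of a disc of radius r (centred at w = 0) lying at
# or above the horizontal line w = c: a circular segment, closed form.
circular_segment_area <- function(r, c) {
  if (r <= 0) return(0)
  if (c <= -r) return(pi * r^2)
  if (c >= r) return(0)
  r^2 * acos(c / r) - c * sqrt(r^2 - c^2)
}

#' Render a synthetic MRI-like stack of a gas-filled eye
#'
#' Renders sagittal slices of a spherical vitreous cavity holding a gas
#' bubble bounded by a flat meniscus perpendicular to gravity. The stack is
#' oriented with the vertical (gravity) axis along image rows and the
#' head-superior direction along increasing columns; the posture flips the
#' eye (supine: anterior up; prone: anterior down) while gravity stays fixed.
#' The globe is rotated by the supraduction angle about the mediolateral
#' (through-slice) axis. Tissue boundaries are anti-aliased by 4 x 4 subpixel
#' supersampling, then Gaussian noise is added and the image blurred.
#'
#' The anterior segment (anterior chamber, iris margins, intraocular lens) is
#' drawn schematically as a shell anterior to the cavity sphere so that
#' anterior-chamber-angle landmarks exist without perturbing the cavity.
#'
#' @param eye An [eye_model()].
#' @param bubble A [gas_bubble()].
#' @param params An [imaging_params()].
#' @param posture \code{"supine"} or \code{"prone"}.
#' @param supraduction_deg Signed supraduction angle in degrees,
#'   \code{|angle| < 45}.
#' @return A list with components \code{stack} (class \code{"image_stack"})
#'   and \code{truth} (class \code{"phantom_truth"}: per-slice cavity and gas
#'   masks, analytic per-slice areas, landmark pixel coordinates on the
#'   mid-sagittal slice, and the generating parameters).
#' @export
render_stack <- function(eye, bubble, params = imaging_params(),
                         posture = c("supine", "prone"),
                         supraduction_deg = 0) {
  posture <- match.arg(posture)
  stopifnot(inherits(eye, "eye_model"), inherits(bubble, "gas_bubble"),
            inherits(params, "imaging_params"))
  if (abs(supraduction_deg) >= 45)
    stop("supraduction angle must satisfy |angle| < 45 degrees")
  R <- eye$radius
  rim <- 1.2                       # scleral shell thickness, mm
  hump <- 3.0                      # anterior-segment shell thickness, mm
  if (2 * (R + rim) >= params$fov_mm)
    stop("eye larger than the field of view")
  n <- params$matrix_size
  dx <- params$pixel_spacing_mm
  ss <- 4L
  ori <- eye_orientation(posture, supraduction_deg)
  plane <- meniscus_plane(eye, bubble)
  cw <- plane$offset_mm            # gas occupies w >= cw (eye-centred)
  phi_l <- eye$limbus_offset / R
  cos_l <- cos(phi_l)

  spacing <- params$slice_spacing_mm
  k <- floor((R - 1e-9) / spacing)
  offsets <- spacing * seq(-k, k)

  # subpixel coordinate vectors (mm, relative to image centre = eye centre)
  u_sub <- (seq_len(n * ss) - 0.5) * dx / ss - n * dx / 2
  w_sub <- rev(u_sub)              # rows run top (w max) to bottom

  if (!is.null(params$seed)) set.seed(params$seed)
  slices <- vector("list", length(offsets))
  cavity_masks <- vector("list", length(offsets))
  gas_masks <- vector("list", length(offsets))
  areas <- data.frame(slice = seq_along(offsets), offset_mm = offsets,
                      cavity_mm2 = 0, gas_mm2 = 0,
                      cavity_px_mm2 = 0, gas_px_mm2 = 0)

  # pixel-centre coordinates for ground-truth masks
  u_px <- (seq_len(n) - (n + 1) / 2) * dx
  w_px <- rev(u_px)

  for (i in seq_along(offsets)) {
    d <- offsets[i]
    d2 <- d^2
    R2 <- outer(w_sub^2, u_sub^2, "+")            # rows = w, cols = u
    img <- matrix(.intensity$background, n * ss, n * ss)
    scl <- R2 <= (R + rim)^2 - d2
    img[scl] <- .intensity$sclera
    # anterior-segment shell: within the cone |angle to pupillary axis| <
    # phi_limbus, radius R .. R + hump
    ax <- outer(w_sub * ori$anterior[2], u_sub * ori$anterior[1], "+")
    D <- sqrt(R2 + d2)
    cone <- ax >= cos_l * D
    ant <- cone & D > R & D <= R + hump
    img[ant] <- .intensity$anterior
    # iris/angle margins and a thin IOL arc, drawn strictly anterior to the
    # scleral shell so the shell stays intact around the cavity
    edge <- cone & ax <= cos(phi_l - 0.05) * D & D > R + rim & D <= R + hump
    img[edge] <- .intensity$iris
    iol <- cone & D > R + rim + 0.3 & D <= R + rim + 0.7
    img[iol] <- .intensity$iris
    # vitreous cavity: fluid below the meniscus, gas at or above it
    cav <- R2 <= R^2 - d2
    gas_rows <- w_sub >= cw
    img[cav & gas_rows] <- .intensity$gas
    img[cav & !gas_rows] <- .intensity$fluid
    # supersampled occupancy fractions give partial-volume-weighted mask areas
    cav_frac <- block_mean(cav + 0, ss)
    gas_frac <- block_mean((cav & gas_rows) + 0, ss)
    areas$cavity_px_mm2[i] <- sum(cav_frac) * dx^2
    areas$gas_px_mm2[i] <- sum(gas_frac) * dx^2
    img <- block_mean(img, ss)
    if (params$noise_sd > 0)
      img <- img + matrix(stats::rnorm(n * n, 0, params$noise_sd), n, n)
    if (params$blur_sigma_px > 0)
      img <- matrix(EBImage::imageData(EBImage::gblur(img, sigma = params$blur_sigma_px)),
                    n, n)
    slices[[i]] <- img

    rp <- if (R^2 - d2 > 0) sqrt(R^2 - d2) else 0
    cav_px <- outer(w_px^2, u_px^2, "+") <= R^2 - d2
    gas_px <- cav_px & matrix(w_px >= cw, n, n)
    cavity_masks[[i]] <- cav_px
    gas_masks[[i]] <- gas_px
    areas$cavity_mm2[i] <- pi * rp^2
    areas$gas_mm2[i] <- circular_segment_area(rp, cw)
  }

  # landmark coordinates on the mid-sagittal slice (continuous pixels)
  mid <- which(offsets == 0)
  ef <- function(x_eye, y_eye)       # eye frame -> world mm
    c(x_eye * ori$anterior[1] + y_eye * ori$superior[1],
      x_eye * ori$anterior[2] + y_eye * ori$superior[2])
  xa <- R * cos_l                    # limbus plane along the axis
  ya <- sqrt((R - 0.5)^2 - xa^2)     # angle recessed 0.5 mm inside the globe
  lm_mm <- rbind(centre = c(0, 0),
                 angle_superior = ef(xa, ya),
                 angle_inferior = ef(xa, -ya),
                 limbus_superior = ef(R * cos_l, R * sin(phi_l)),
                 limbus_inferior = ef(R * cos_l, -R * sin(phi_l)),
                 anterior_pole = ef(R, 0),
                 posterior_pole = ef(-R, 0))
  lm_px <- mm_to_px(lm_mm, n, dx)
  rownames(lm_px) <- rownames(lm_mm)

  stack <- structure(list(slices = slices,
                          pixel_spacing_mm = dx,
                          slice_spacing_mm = spacing,
                          slice_offsets_mm = offsets,
                          posture = posture,
                          superior_dir = "+col"),
                     class = "image_stack")
  truth <- structure(list(fill_fraction = bubble$fill_fraction,
                          supraduction_deg = supraduction_deg,
                          posture = posture,
                          eye = eye, bubble = bubble,
                          meniscus_offset_mm = cw,
                          mid_slice = mid,
                          cavity_masks = cavity_masks,
                          gas_masks = gas_masks,
                          areas = areas,
                          landmarks_px = lm_px,
                          pixel_spacing_mm = dx),
                     class = "phantom_truth")
  list(stack = stack, truth = truth)
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d slices of %d x %d px (%.4f mm px, %.1f mm spacing), %s\n",
              length(x$slices), nrow(x$slices[[1]]), ncol(x$slices[[1]]),
              x$pixel_spacing_mm, x$slice_spacing_mm, x$posture))
  invisible(x)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> fill %.1f%%, %s, supraduction %+.1f deg, %d slices\n",
              100 * x$fill_fraction, x$posture, x$supraduction_deg,
              length(x$cavity_masks)))
  invisible(x)
}

#' Write / read an image stack as multi-page TIFF plus JSON sidecar
#'
#' Intensities are stored as 16-bit grey (clipped to 0-255, scaled to
#' \code{[0, 1]}); the sidecar records spacings, posture and, when a
#' \code{truth} object is supplied, the generating ground truth (fill
#' fraction, supraduction angle, landmark pixel coordinates).
#'
#' @param stack An \code{image_stack}.
#' @param path Output TIFF path; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @param truth Optional \code{phantom_truth}.
#' @return \code{path}, invisibly.
#' @export
write_image_stack <- function(stack, path, truth = NULL) {
  imgs <- lapply(stack$slices, function(m) pmax(pmin(m / 255, 1), 0))
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  side <- list(pixel_spacing_mm = stack$pixel_spacing_mm,
               slice_spacing_mm = stack$slice_spacing_mm,
               slice_offsets_mm = stack$slice_offsets_mm,
               posture = stack$posture,
               superior_dir = stack$superior_dir)
  if (!is.null(truth)) {
    side$truth <- list(fill_fraction = truth$fill_fraction,
                       supraduction_deg = truth$supraduction_deg,
                       mid_slice = truth$mid_slice,
                       meniscus_offset_mm = truth$meniscus_offset_mm,
                       landmarks_px = as.data.frame(truth$landmarks_px))
  }
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(slices = lapply(imgs, function(m) m * 255),
                 pixel_spacing_mm = side$pixel_spacing_mm,
                 slice_spacing_mm = side$slice_spacing_mm,
                 slice_offsets_mm = side$slice_offsets_mm,
                 posture = side$posture,
                 superior_dir = side$superior_dir,
                 sidecar = side),
            class = "image_stack")
}

#' Phantom scenarios from the per-case clinical table
#'
#' Builds one phantom scenario per printed (case, posture) pair: the gas
#' fill fraction and supraduction angle come from the gas-volume/angle table
#' and the axial length from the patient-characteristics table.
#'
#' @param table3 Path to (or data frame of) the per-case gas volume and
#'   supraduction angle table, columns \code{case},
#'   \code{gas_volume_prone_pct}, \code{gas_volume_supine_pct},
#'   \code{angle_prone_deg}, \code{angle_supine_deg}.
#' @param table1 Path to (or data frame of) the patient characteristics
#'   table, columns \code{case} and \code{axial_length_mm}.
#' @return A list of scenarios: \code{case}, \code{posture}, \code{eye},
#'   \code{fill_fraction}, \code{supraduction_deg}.
#' @export
cohort_from_table3 <- function(table3 = gt_table_path("table3"),
                               table1 = gt_table_path("table1")) {
  t3 <- if (is.character(table3)) utils::read.csv(table3) else table3
  t1 <- if (is.character(table1)) utils::read.csv(table1) else table1
  need3 <- c("case", "gas_volume_prone_pct", "gas_volume_supine_pct",
             "angle_prone_deg", "angle_supine_deg")
  if (!all(need3 %in% names(t3)))
    stop("malformed gas-volume table: missing column(s) ",
         paste(setdiff(need3, names(t3)), collapse = ", "))
  if (!all(c("case", "axial_length_mm") %in% names(t1)))
    stop("malformed patient table: needs 'case' and 'axial_length_mm'")
  for (cc in need3) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(t3[[cc]]))))
    if (length(bad))
      stop("malformed gas-volume table: non-numeric '", cc, "' in row ", bad[1])
  }
  scenarios <- list()
  for (i in seq_len(nrow(t3))) {
    case <- t3$case[i]
    al <- t1$axial_length_mm[match(case, t1$case)]
    if (!is.finite(al)) stop("no axial length for case ", case)
    eye <- eye_model(al)
    for (posture in c("prone", "supine")) {
      f <- t3[[paste0("gas_volume_", posture, "_pct")]][i] / 100
      ang <- t3[[paste0("angle_", posture, "_deg")]][i]
      scenarios[[length(scenarios) + 1L]] <-
        list(case = case, posture = posture, eye = eye,
             fill_fraction = f, supraduction_deg = ang)
    }
  }
  scenarios
}

#' Path to a bundled clinical table fixture
#'
#' @param name One of \code{"table1"}, \code{"table2"}, \code{"table3"}.
#' @return File path of the CSV fixture.
#' @export
gt_table_path <- function(name = c("table1", "table2", "table3")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".csv"), package = "gastamponade",
              mustWork = TRUE)
}
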