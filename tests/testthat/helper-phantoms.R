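# Shared phantom cache: rendering a 320x320 stack is the expensive step, and
# several test files probe the same configurations.
.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(fill, posture = "supine", angle = 0, noise = 0,
                           seed = 1L, axial_length = 25.4) {
  key <- paste(fill, posture, angle, noise, seed, axial_length, sep = "|")
  if (!is.null(.phantom_cache[[key]])) return(.phantom_cache[[key]])
  eye <- eye_model(axial_length)
  bubble <- gas_bubble(fill, eye)
  params <- imaging_params(seed = seed, noise_sd = noise)
  r <- render_stack(eye, bubble, params, posture, angle)
  seg <- suppressWarnings(segment_stack(r$stack))
  out <- list(eye = eye, bubble = bubble, render = r, seg = seg)
  .phantom_cache[[key]] <- out
  out
}

# Slice geometry of the mid-sagittal slice, built the same way the pipeline
# builds it (sidecar angle landmarks, fractional coverage maps, raw image).
phantom_geometry <- function(ph) {
  mid <- ph$render$truth$mid_slice
  lm <- ph$render$truth$landmarks_px
  m <- ph$seg$masks[[mid]]
  slice_geometry(m$cavity, m$gas, ph$render$stack$pixel_spacing_mm,
                 lm["angle_superior", ], lm["angle_inferior", ],
                 gas_frac = m$gas_frac, cavity_frac = m$cavity_frac,
                 image = ph$render$stack$slices[[mid]])
}

# One cohort run shared between the closed-loop and posture-pattern
# acceptance tests (16 phantoms at default resolution, noise-free so the
# pixel/oracle comparison is not seed-dependent).
cached_cohort_noise0 <- function() {
  if (!is.null(.phantom_cache[["cohort0"]])) return(.phantom_cache[["cohort0"]])
  co <- suppressWarnings(
    run_cohort(params = imaging_params(seed = 11L, noise_sd = 0)))
  .phantom_cache[["cohort0"]] <- co
  co
}
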