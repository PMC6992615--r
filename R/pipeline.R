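#' Run the full measurement pipeline on one phantom scenario
#'
#' Renders the stack, segments it, selects the biometric slice, builds the
#' slice geometry from the sidecar anterior-chamber-angle landmarks, and
#' measures gas volume, supraduction angle and the four gas contact rates.
#'
#' @param scenario One element of [cohort_from_table3()] (or a list with
#'   \code{case}, \code{posture}, \code{eye}, \code{fill_fraction},
#'   \code{supraduction_deg}).
#' @param params An [imaging_params()]; the scenario index folds the seed so
#'   every (case, posture) stack is distinct yet reproducible.
#' @param tolerance_px Contact tolerance passed to [measure_contact()].
#' @param keep_stack Keep the rendered stack and masks in the result.
#' @return A list: \code{row} (one-row data frame of measurements) and,
#'   optionally, the intermediate objects.
#' @export
analyze_scenario <- function(scenario, params = imaging_params(),
                             tolerance_px = 1, keep_stack = FALSE) {
  eye <- scenario$eye
  bubble <- gas_bubble(scenario$fill_fraction, eye)
  p <- params
  p$seed <- as.integer(params$seed + 101L * as.integer(scenario$case) +
                         (scenario$posture == "supine"))
  r <- render_stack(eye, bubble, p, scenario$posture, scenario$supraduction_deg)
  seg <- segment_stack(r$stack)
  lm <- r$truth$landmarks_px
  dx <- r$stack$pixel_spacing_mm
  n_img <- nrow(r$stack$slices[[1]])

  # preliminary axis from the largest-cavity slice centroid and the sidecar
  # angle landmarks; then pick the slice whose extent matches the biometry
  big <- which.max(seg$per_slice$cavity_mm2)
  g0 <- slice_geometry(seg$masks[[big]]$cavity, seg$masks[[big]]$gas, dx,
                       lm["angle_superior", ], lm["angle_inferior", ])
  idx <- select_slice(seg, eye$axial_length, g0$anterior)
  g <- slice_geometry(seg$masks[[idx]]$cavity, seg$masks[[idx]]$gas, dx,
                      lm["angle_superior", ], lm["angle_inferior", ],
                      gas_frac = seg$masks[[idx]]$gas_frac,
                      cavity_frac = seg$masks[[idx]]$cavity_frac,
                      image = r$stack$slices[[idx]])
  part <- partition_retina(g)
  contact <- measure_contact(g, part, tolerance_px = tolerance_px)
  angle <- measure_supraduction(g, scenario$posture)
  analytic <- analytic_contact_rates(eye, bubble, scenario$posture,
                                     scenario$supraduction_deg)

  row <- data.frame(case = scenario$case, posture = scenario$posture,
                    fill_pct_true = 100 * scenario$fill_fraction,
                    angle_true_deg = scenario$supraduction_deg,
                    gas_volume_pct = seg$gas_volume_pct,
                    angle_deg = angle,
                    slice = as.integer(idx),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(contact))) {
    row[[paste0("rate_", contact$part[i])]] <- contact$rate_pct[i]
    row[[paste0("analytic_", contact$part[i])]] <- analytic$rate_pct[i]
  }
  out <- list(row = row, contact = contact, analytic = analytic)
  if (keep_stack) out <- c(out, list(stack = r$stack, truth = r$truth,
                                     segmentation = seg, geometry = g))
  out
}

#' Run the phantom cohort and reproduce the posture comparison
#'
#' Executes [analyze_scenario()] for every scenario (by default the printed
#' per-case cohort: 8 cases x 2 postures), then summarizes each metric as
#' mean +/- SE per posture and compares postures. The posture comparison
#' uses the unpaired Mann-Whitney U test, mirroring the original analysis
#' even though the prone/supine data are paired by eye; the paired Wilcoxon
#' signed-rank p is reported alongside as a methodological note.
#'
#' @param scenarios List of scenarios, default [cohort_from_table3()].
#' @param params An [imaging_params()].
#' @param tolerance_px Contact tolerance, pixels.
#' @param out_dir Optional directory: per-case CSV, summary CSV and a JSON
#'   manifest are written there.
#' @param verbose Print one line per scenario.
#' @return Object of class \code{"gas_cohort"}: \code{results} (per-case
#'   rows), \code{comparison} (per-metric means, SEs and p-values),
#'   \code{params}.
#' @export
run_cohort <- function(scenarios = cohort_from_table3(),
                       params = imaging_params(), tolerance_px = 1,
                       out_dir = NULL, verbose = FALSE) {
  rows <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    res <- tryCatch(
      analyze_scenario(sc, params, tolerance_px = tolerance_px),
      error = function(e) stop("pipeline failed at case ", sc$case, " (",
                               sc$posture, "): ", conditionMessage(e)))
    rows[[i]] <- res$row
    if (verbose)
      message(sprintf("case %s %s: gas %.1f%% (true %.1f), angle %+.1f deg",
                      sc$case, sc$posture, res$row$gas_volume_pct,
                      res$row$fill_pct_true, res$row$angle_deg))
  }
  results <- do.call(rbind, rows)
  enough <- min(sum(results$posture == "prone"),
                sum(results$posture == "supine")) >= 2
  comparison <- if (enough) compare_postures(results) else NULL
  out <- structure(list(results = results, comparison = comparison,
                        params = params, tolerance_px = tolerance_px),
                   class = "gas_cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(out_dir, "per_case.csv"),
                     row.names = FALSE)
    if (!is.null(comparison))
      utils::write.csv(comparison, file.path(out_dir, "posture_comparison.csv"),
                       row.names = FALSE)
    manifest <- list(package_version = as.character(utils::packageVersion("gastamponade")),
                     params = unclass(params), tolerance_px = tolerance_px,
                     n_scenarios = length(scenarios),
                     cases = vapply(scenarios, function(s)
                       paste0(s$case, ":", s$posture), character(1)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Posture comparison table for cohort results
#'
#' Mean +/- SE per posture and prone-vs-supine p-values (unpaired
#' Mann-Whitney U as in the original analysis; paired Wilcoxon signed-rank
#' alongside) for the gas volume, supraduction angle and the four contact
#' rates.
#'
#' @param results Per-case data frame from [run_cohort()].
#' @return Data frame, one row per metric.
#' @export
compare_postures <- function(results) {
  metrics <- c(gas_volume_pct = "Gas volume (% to vitreous cavity)",
               angle_deg = "Angle of supraduction (deg)",
               rate_superior_posterior = "Gas contact rate, superior-posterior (%)",
               rate_superior_anterior = "Gas contact rate, superior-anterior (%)",
               rate_inferior_posterior = "Gas contact rate, inferior-posterior (%)",
               rate_inferior_anterior = "Gas contact rate, inferior-anterior (%)")
  metrics <- metrics[names(metrics) %in% names(results)]
  pr <- results[results$posture == "prone", ]
  su <- results[results$posture == "supine", ]
  pr <- pr[order(pr$case), ]; su <- su[order(su$case), ]
  rows <- lapply(names(metrics), function(mc) {
    a <- pr[[mc]]; b <- su[[mc]]
    mwu <- mann_whitney_u(a, b)
    wsr <- tryCatch(wilcoxon_signed_rank(a, b)$p_value,
                    error = function(e) NA_real_)
    data.frame(metric = metrics[[mc]], key = mc,
               mean_prone = mean(a), se_prone = stats::sd(a) / sqrt(length(a)),
               mean_supine = mean(b), se_supine = stats::sd(b) / sqrt(length(b)),
               p_mann_whitney = mwu$p_value,
               p_wilcoxon_paired = wsr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.gas_cohort <- function(x, ...) {
  cat(sprintf("<gas_cohort> %d measurements (%d cases x 2 postures)\n",
              nrow(x$results), length(unique(x$results$case))))
  cmp <- x$comparison
  if (is.null(cmp)) return(invisible(x))
  for (i in seq_len(nrow(cmp)))
    cat(sprintf("  %-45s prone %5.1f ± %4.1f  supine %5.1f ± %4.1f  p = %.4g\n",
                cmp$metric[i], cmp$mean_prone[i], cmp$se_prone[i],
                cmp$mean_supine[i], cmp$se_supine[i], cmp$p_mann_whitney[i]))
  invisible(x)
}
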