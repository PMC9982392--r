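# Comparative gastric-emptying metrics for a CGJ/SPGJ model pair: pyloric
# flow split, inlet-to-outlet pressure drop, particle retention time and
# mean instantaneous particle speed, assembled into a comparison report.

#' Area-weighted inlet-to-outlet pressure drop
#'
#' Mean gauge pressure over the inlet-adjacent cell layer minus the mean
#' over the outlet-adjacent layer (the gauge reference), each extrapolated
#' half a cell to the port plane along the local pressure gradient.
#'
#' @param field a converged `flow_field`
#' @param mesh the `volume_mesh` it was solved on
#' @return pressure drop, Pa
#' @export
pressure_drop <- function(field, mesh) {
  if (!field$converged) stop("flow field is not converged; refusing to report a pressure drop")
  if (field$Q_in == 0) return(0)
  d <- mesh$dims
  port_mean <- function(k_port, k_next) {
    sel <- which(mesh$mask[, , k_port])
    i <- (sel - 1L) %% d[1] + 1L
    j <- (sel - 1L) %/% d[1] + 1L
    p0 <- field$p[cbind(i, j, k_port)]
    p1 <- field$p[cbind(i, j, k_next)]
    ok <- mesh$mask[cbind(i, j, k_next)]
    # linear extrapolation to the port plane where the next cell exists
    mean(ifelse(ok, p0 + 0.5 * (p0 - p1), p0))
  }
  port_mean(d[3], d[3] - 1L) - port_mean(1L, 2L)
}

#' Assemble the emptying metrics of one reconstruction
#'
#' @param variant `"CGJ"` or `"SPGJ"`
#' @param field converged `flow_field`
#' @param mesh its `volume_mesh`
#' @param cohort a `particle_cohort` tracked through the field
#' @return object of class `model_result`: pyloric and anastomotic flux
#'   (m^3/s), their closure against the inlet flux, pressure drop (Pa),
#'   mean retention time (s) and mean instantaneous particle speed (m/s)
#'   over escaped particles
#' @export
model_result <- function(variant, field, mesh, cohort) {
  variant <- match.arg(variant, c("CGJ", "SPGJ"))
  qp <- cross_section_flux(field, mesh, "PYLORUS")
  qa <- cross_section_flux(field, mesh, "ANASTOMOSIS")
  closure <- abs(qp + qa - field$Q_in) / field$Q_in
  if (closure > 0.005) {
    warning("flux split closure violated: pyloric + anastomotic differs from ",
            "inlet flux by ", signif(100 * closure, 3), "%")
  }
  stats <- retention_and_speed_stats(cohort)
  structure(list(variant = variant, pyloric_flux = qp, anastomotic_flux = qa,
                 inlet_flux = field$Q_in, flux_closure = closure,
                 pressure_drop = pressure_drop(field, mesh),
                 mean_retention = stats$mean_retention,
                 mean_speed = stats$mean_speed,
                 n_escaped = stats$n_escaped,
                 field = field, mesh = mesh, cohort = cohort),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(x$variant, "model:\n")
  cat(sprintf("  pyloric flux %.3g m^3/s (%.1f%% of inflow), anastomotic %.3g m^3/s\n",
              x$pyloric_flux, 100 * x$pyloric_flux / x$inlet_flux, x$anastomotic_flux))
  cat(sprintf("  pressure drop %.3f Pa; mean retention %.1f s; mean speed %.1f mm/s\n",
              x$pressure_drop, x$mean_retention, 1000 * x$mean_speed))
  invisible(x)
}

#' Retention-time and speed statistics of a tracked cohort
#'
#' Mean injection-to-escape time and mean instantaneous speed (average over
#' the uniform-interval speed samples of each trajectory), both over escaped
#' particles only.
#'
#' @param cohort a `particle_cohort` (or its `summary` tibble)
#' @return list with `mean_retention` (s), `mean_speed` (m/s), `n_escaped`
#' @export
retention_and_speed_stats <- function(cohort) {
  s <- if (inherits(cohort, "particle_cohort")) cohort$summary else cohort
  esc <- s$status %in% c("ESCAPED_OUTLET", "ESCAPED_INLET")
  if (!any(esc)) {
    stop("no particle escaped; raise max_time in the tracking configuration")
  }
  list(mean_retention = mean(s$retention_time[esc]),
       mean_speed = mean(s$mean_speed[esc], na.rm = TRUE),
       n_escaped = sum(esc))
}

#' Pyloric flow ratio of an SPGJ/CGJ pair
#'
#' Flow through the pyloric cross-section in the SPGJ model as a percentage
#' of that in the CGJ model. The comparison uses flux magnitudes: on the
#' synthetic anatomy the steady pyloric flow is a junction-driven
#' recirculation whose sign can be retrograde (flow re-entering the stomach
#' through the pylorus), and the blocking effect of the partition is the
#' magnitude ratio. A warning reports retrograde flow.
#'
#' @param cgj,spgj `model_result` objects of the respective variants
#' @return percentage (100 = identical)
#' @export
pyloric_flow_ratio <- function(cgj, spgj) {
  if (cgj$variant != "CGJ" || spgj$variant != "SPGJ") {
    stop("arguments must be the CGJ and SPGJ model results, in that order")
  }
  if (abs(cgj$pyloric_flux) < 1e-3 * cgj$inlet_flux) {
    stop("CGJ pyloric flux is numerically zero; the ratio is undefined")
  }
  if (cgj$pyloric_flux < 0 || spgj$pyloric_flux < 0) {
    warning("retrograde pyloric flow (duodenum toward stomach); ",
            "ratio computed on magnitudes")
  }
  100 * abs(spgj$pyloric_flux) / abs(cgj$pyloric_flux)
}

#' Comparison report for a CGJ/SPGJ pair
#'
#' The four comparative emptying metrics: pyloric flow ratio (SPGJ as a
#' percentage of CGJ), relative pressure-drop reduction, retention-time
#' ratio (CGJ over SPGJ) and the mean instantaneous particle speeds in
#' mm/s. A pure function of the two model results.
#'
#' @param cgj,spgj `model_result` objects
#' @return object of class `comparison_report`
#' @export
build_report <- function(cgj, spgj) {
  if (identical(cgj$variant, spgj$variant)) {
    stop("the two model results must come from different reconstructions")
  }
  structure(list(
    pyloric_flow_ratio_pct = pyloric_flow_ratio(cgj, spgj),
    pressure_drop_reduction_pct = 100 * (1 - spgj$pressure_drop / cgj$pressure_drop),
    retention_time_ratio = cgj$mean_retention / spgj$mean_retention,
    mean_speed_cgj_mms = 1000 * cgj$mean_speed,
    mean_speed_spgj_mms = 1000 * spgj$mean_speed,
    pressure_drop_cgj_pa = cgj$pressure_drop,
    pressure_drop_spgj_pa = spgj$pressure_drop,
    pyloric_share_cgj_pct = 100 * cgj$pyloric_flux / cgj$inlet_flux,
    pyloric_share_spgj_pct = 100 * spgj$pyloric_flux / spgj$inlet_flux,
    mean_retention_cgj_s = cgj$mean_retention,
    mean_retention_spgj_s = spgj$mean_retention), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("CGJ vs SPGJ gastric-emptying comparison\n")
  cat(sprintf("  pyloric flow, SPGJ / CGJ:        %.1f%%\n", x$pyloric_flow_ratio_pct))
  cat(sprintf("  pressure-drop reduction (SPGJ):  %.1f%%  (%.3f vs %.3f Pa)\n",
              x$pressure_drop_reduction_pct, x$pressure_drop_spgj_pa,
              x$pressure_drop_cgj_pa))
  cat(sprintf("  mean retention ratio CGJ/SPGJ:   %.2f  (%.1f vs %.1f s)\n",
              x$retention_time_ratio, x$mean_retention_cgj_s,
              x$mean_retention_spgj_s))
  cat(sprintf("  mean particle speed:             CGJ %.1f, SPGJ %.1f mm/s\n",
              x$mean_speed_cgj_mms, x$mean_speed_spgj_mms))
  invisible(x)
}

#' Write a comparison report to JSON and CSV
#'
#' @param report a `comparison_report`
#' @param path_json,path_csv output files (`NULL` to skip either)
#' @return the report, invisibly
#' @export
write_report <- function(report, path_json = NULL, path_csv = NULL) {
  vals <- unclass(report)
  if (!is.null(path_json)) {
    jsonlite::write_json(vals, path_json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(path_csv)) {
    utils::write.csv(data.frame(metric = names(vals),
                                value = unlist(vals), row.names = NULL),
                     path_csv, row.names = FALSE)
  }
  invisible(report)
}
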