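#' Run the full life-table pipeline and write a report directory
#'
#' Computes the age-stage schedules, all scalar parameters with bootstrap
#' standard errors, life expectancy, reproductive value and a population
#' projection, and writes five artifacts to `out_dir`:
#' `params.json` (point estimates and bootstrap summaries; every number equals
#' the corresponding function's return value), `age_stage_schedule.csv`
#' (age, stage, s, f, e, v), `age_schedule.csv` (age, l, m, net maternity),
#' `run_info.json` (label, seed, B, horizon, initial composition) and
#' `lifetable_plots.pdf` (s_xj; l_x, m_x, l_x m_x; e_xj; v_xj; log total
#' population). Identical configurations write identical JSON and CSV files.
#'
#' @param cohort a [cohort_table()]; if `NULL`, one is simulated from `preset`
#' @param preset preset name for [cohort_preset()] when `cohort` is `NULL`
#' @param out_dir output directory (created if needed)
#' @param B bootstrap resamples
#' @param seed seed for simulation and bootstrap
#' @param horizon projection horizon in days
#' @param initial initial age-stage composition for the projection
#' @return invisibly, a named list of the artifact paths
#' @export
run_lifetable <- function(cohort = NULL, preset = "dsEGFP-like", out_dir,
                          B = 1000L, seed = 42L, horizon = 100L,
                          initial = c(egg = 10)) {
  if (is.null(cohort)) {
    cohort <- simulate_cohort(cohort_preset(preset), seed = seed)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  sched <- build_schedule(cohort)
  pars <- lifetable_params(cohort, sched)
  boot <- bootstrap_params(cohort, B = B, seed = seed, keep_resamples = FALSE)
  e <- life_expectancy(sched)
  v <- reproductive_value(sched, pars$r)
  proj <- project_population(sched, initial, days = horizon)

  paths <- c(params = file.path(out_dir, "params.json"),
             age_stage = file.path(out_dir, "age_stage_schedule.csv"),
             age = file.path(out_dir, "age_schedule.csv"),
             run_info = file.path(out_dir, "run_info.json"),
             plots = file.path(out_dir, "lifetable_plots.pdf"))

  utils::write.csv(schedule_frame(sched, e = e, v = v), paths["age_stage"],
                   row.names = FALSE)
  utils::write.csv(data.frame(age = sched$ages, l = sched$l, m = sched$m,
                              net_maternity = sched$net_maternity),
                   paths["age"], row.names = FALSE)
  jsonlite::write_json(
    list(point = unclass(pars), bootstrap = boot$parameters,
         degenerate_resamples = boot$degenerate,
         projection_final_total = proj$total[length(proj$total)]),
    paths["params"], auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(
    list(label = cohort$label, N = pars$N, seed = seed, B = B,
         horizon = horizon, initial = as.list(initial)),
    paths["run_info"], auto_unbox = TRUE, digits = NA)

  grDevices::pdf(paths["plots"], width = 9, height = 6)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  plot_schedule_panels(sched, e, v)
  graphics::plot(0:proj$days, pmax(proj$total, 1e-12), log = "y", type = "l",
                 xlab = "day", ylab = "total count (log)",
                 main = "projected population")
  invisible(as.list(paths))
}

# Fig-5-style base-graphics panels; called inside an open device.
plot_schedule_panels <- function(sched, e = NULL, v = NULL) {
  ages <- sched$ages
  graphics::matplot(ages, sched$s, type = "l", lty = 1,
                    xlab = "age (d)", ylab = expression(s[xj]),
                    main = "age-stage survival")
  graphics::legend("topright", legend = sched$stages, col = seq_along(sched$stages),
                   lty = 1, cex = 0.7, bty = "n")
  graphics::matplot(ages, cbind(sched$l, sched$m, sched$net_maternity),
                    type = "l", lty = 1,
                    xlab = "age (d)", ylab = "",
                    main = expression(l[x] * ", " * m[x] * ", " * l[x] * m[x]))
  graphics::legend("topright", legend = c("l", "m", "l*m"), col = 1:3, lty = 1,
                   cex = 0.7, bty = "n")
  if (is.null(e)) e <- life_expectancy(sched)
  graphics::matplot(ages, e, type = "l", lty = 1, xlab = "age (d)",
                    ylab = expression(e[xj]), main = "life expectancy")
  if (is.null(v)) v <- reproductive_value(sched)
  graphics::matplot(ages, v, type = "l", lty = 1, xlab = "age (d)",
                    ylab = expression(v[xj]), main = "reproductive value")
  invisible(NULL)
}

#' Table-style comparison of two cohorts
#'
#' Bootstraps both cohorts with paired resamples and emits one row per
#' parameter: group means and SEs of the resample estimates, the point
#' estimates, and the paired bootstrap test p-value -- the machine-readable
#' analogue of a published life-table comparison table.
#'
#' @inheritParams paired_bootstrap_test
#' @param file optional path; when given, the table is also written as CSV
#' @return data.frame with columns `parameter`, `estimate_A`, `mean_A`, `se_A`,
#'   `estimate_B`, `mean_B`, `se_B`, `difference`, `p_value`, `significant`
#' @export
compare_cohorts <- function(cohortA, cohortB, B = 1000L, seed = 42L,
                            params = NULL, file = NULL) {
  pb <- .paired_boot(cohortA, cohortB, B, seed, params)
  D <- pb$SA - pb$SB
  msd <- function(M) list(m = apply(M, 2, mean, na.rm = TRUE),
                          s = apply(M, 2, stats::sd, na.rm = TRUE))
  a <- msd(pb$SA)
  b <- msd(pb$SB)
  pv <- vapply(seq_along(pb$params), function(k) {
    d <- D[, k]
    d <- d[!is.na(d)]
    if (!length(d)) return(NA_real_)
    min(max(2 * min(mean(d <= 0), mean(d >= 0)), 2 / B), 1)
  }, numeric(1))
  out <- data.frame(parameter = pb$params,
                    estimate_A = unname(pb$estA), mean_A = unname(a$m),
                    se_A = unname(a$s),
                    estimate_B = unname(pb$estB), mean_B = unname(b$m),
                    se_B = unname(b$s),
                    difference = unname(a$m - b$m), p_value = pv,
                    significant = pv < 0.05, row.names = NULL)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
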