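#' Configuration of a computational experiment
#'
#' Bundles everything one uncertainty/sensitivity experiment needs: the
#' landscape (an object, or a generator config plus seed), the factor
#' space (with any factors already fixed), the Saltelli base sample size,
#' and the master seed of the simulator.
#'
#' @param name Experiment label.
#' @param landscape A `crp_landscape`, or `NULL` to synthesise one from
#'   `landscape_cfg` and `landscape_seed`.
#' @param space Factor-space tibble (default [crp_factors()]).
#' @param N Saltelli base sample size (default 128, giving the canonical
#'   2560-run baseline at nine free factors).
#' @param master_seed Seed of the deterministic simulator streams.
#' @param landscape_cfg,landscape_seed Generator inputs used when
#'   `landscape` is `NULL`.
#' @param years Simulation horizon.
#' @param n_boot Bootstrap resamples for index standard errors.
#' @param out_dir Optional directory for reports and checkpoints.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(name = "EXP1", landscape = NULL,
                              space = crp_factors(), N = 128L,
                              master_seed = 1L,
                              landscape_cfg = landscape_config(),
                              landscape_seed = 1L, years = 10L,
                              n_boot = 500L, out_dir = NULL) {
  stopifnot(N >= 2)
  validate_factor_space(space)
  structure(list(name = name, landscape = landscape, space = space,
                 N = as.integer(N), master_seed = as.integer(master_seed),
                 landscape_cfg = landscape_cfg,
                 landscape_seed = as.integer(landscape_seed),
                 years = as.integer(years), n_boot = as.integer(n_boot),
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Run one uncertainty/sensitivity experiment end-to-end
#'
#' Builds the Saltelli design over the free factors, evaluates the
#' enrollment simulator on every row (total fallow area in acres as the
#' scalar output), and computes the uncertainty summary and the Sobol'
#' index decomposition.  Fully deterministic given the config: re-running
#' reproduces every number.
#'
#' @param config An [experiment_config()].
#' @param context Optional prebuilt `crp_context` (to share across
#'   experiments on the same landscape).
#' @param checkpoint Optional checkpoint CSV path for restartable
#'   evaluation.
#' @return An object of class `experiment_report`: the config, the run log
#'   (design rows with outputs), `ua` (uncertainty summary), `sa`
#'   (`sensitivity_result`) and `run_count`.
#' @export
run_experiment <- function(config, context = NULL, checkpoint = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(context)) {
    landscape <- config$landscape
    if (is.null(landscape)) {
      landscape <- generate_landscape(config$landscape_cfg,
                                      config$landscape_seed)
    }
    context <- landscape_context(landscape)
  }
  space <- config$space
  free <- free_factors(space)
  k <- length(free)
  if (k < 1) stop("no free factors left to design over", call. = FALSE)
  design <- saltelli_design(k, config$N)
  values <- transform_design(
    space, as.matrix(design$rows[, paste0("u", seq_len(k))]))

  model <- function(u_row) {
    vals <- transform_design(space, matrix(u_row, nrow = 1L))
    res <- run_simulation(context, vals, master_seed = config$master_seed,
                          years = config$years, keep_raster = FALSE)
    res$area_acres
  }
  runs <- evaluate_design(design, model, checkpoint = checkpoint)
  runs <- dplyr::bind_cols(runs, values)

  ua <- uncertainty_summary(runs$output)
  sa <- sobol_indices(runs, factor_names = free, n_boot = config$n_boot,
                      boot_seed = config$master_seed + 17L)
  structure(list(config = config, runs = runs, ua = ua, sa = sa,
                 run_count = nrow(runs), context = NULL),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment", x$config$name, ":", x$run_count, "runs (N =",
      x$config$N, ", k =", x$sa$k, ")\n")
  cat("  AREA mean", round(x$ua$mean, 1), "acres, variance",
      signif(x$ua$variance, 5), "\n")
  cat("  interaction share I =", signif(x$sa$I, 3), "\n")
  invisible(x)
}

#' Tidy an experiment report
#' @param x An `experiment_report`.
#' @param ... Unused.
#' @return The per-factor sensitivity tibble.
#' @export
tidy.experiment_report <- function(x, ...) {
  tidy(x$sa)
}

#' One-row summary of an experiment report
#' @inheritParams tidy.experiment_report
#' @return A one-row tibble: run count, output mean/variance, quantile
#'   spread, sum of first-order indices and interaction share.
#' @export
glance.experiment_report <- function(x, ...) {
  tibble::tibble(
    name = x$config$name, runs = x$run_count, N = x$config$N, k = x$sa$k,
    mean = x$ua$mean, variance = x$ua$variance, sd = x$ua$sd,
    q2.5 = x$ua$quantiles$value[1], q97.5 = x$ua$quantiles$value[5],
    sum_S = sum(x$sa$factors$S), interaction = x$sa$I
  )
}

#' Histogram of the experiment's output distribution
#' @param object An `experiment_report`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_report <- function(object, bins = 30, ...) {
  d <- tibble::tibble(area = object$runs$output)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$area)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = object$ua$mean, linetype = 2) +
    ggplot2::labs(x = "total fallow area (acres)", y = "runs",
                  title = paste("Output distribution,",
                                object$config$name)) +
    ggplot2::theme_minimal()
}

#' Exploratory simplification: fix the negligible factors
#'
#' Derives a simplified experiment in which every factor whose first-order
#' and total-effect indices both fall below `threshold` is fixed at its
#' distribution median (or mean), leaving the influential factors free.
#' Fixing only negligible factors preserves the output distribution —
#' the simplified model keeps the baseline's exploratory power.
#'
#' @param report A baseline `experiment_report`.
#' @param threshold Negligibility threshold on both indices.
#' @param fix_at `"median"` (default) or `"mean"`.
#' @return A derived [experiment_config()].
#' @export
simplify_exploratory <- function(report, threshold = 0.01,
                                 fix_at = c("median", "mean")) {
  stopifnot(inherits(report, "experiment_report"))
  fix_at <- match.arg(fix_at)
  ranked <- rank_factors(report$sa, threshold)
  negligible <- ranked$name[ranked$negligible]
  if (length(negligible) == nrow(ranked)) {
    stop("all factors are negligible at this threshold", call. = FALSE)
  }
  cfg <- report$config
  space <- cfg$space
  for (nm in negligible) {
    value <- if (fix_at == "median") factor_median(space, nm) else
      factor_mean(space, nm)
    space <- fix_factor(space, nm, value)
  }
  cfg$space <- space
  cfg$name <- paste0(cfg$name, "-exploratory")
  cfg
}

#' Explanatory refinement: fix the dominant factor
#'
#' Derives an experiment in which the factor with the highest first-order
#' index is fixed at its support midpoint (the middle of the ordered
#' support for a discrete factor), with every other factor left free.
#' Pinning the dominant factor reduces output variance while preserving
#' the mean, exposing the interactions among the remaining factors.
#' Argmax ties are broken by factor-space order.
#'
#' @param report A baseline `experiment_report`.
#' @return A derived [experiment_config()].
#' @export
refine_explanatory <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  cfg <- report$config
  space <- cfg$space
  f <- report$sa$factors
  # order factors as in the factor space so ties pick the lower index
  pos <- match(f$name, space$name)
  top <- f$name[order(-f$S, pos)][1]
  cfg$space <- fix_factor(space, top, support_midpoint(space, top))
  cfg$name <- paste0(cfg$name, "-explanatory")
  cfg
}

#' Compare an experiment against a baseline
#'
#' Mean difference (with its two-sample standard error), variance ratio
#' and the spread-reduction percentage
#' `100 * (1 - var / var_baseline)`.
#'
#' @param report,baseline Two `experiment_report`s sharing the output
#'   definition.
#' @return A one-row tibble.
#' @export
compare_reports <- function(report, baseline) {
  stopifnot(inherits(report, "experiment_report"),
            inherits(baseline, "experiment_report"))
  if (baseline$ua$variance == 0) {
    stop("baseline variance is zero; comparison undefined", call. = FALSE)
  }
  se <- sqrt(report$ua$variance / report$ua$n +
               baseline$ua$variance / baseline$ua$n)
  tibble::tibble(
    name = report$config$name,
    baseline_name = baseline$config$name,
    mean = report$ua$mean,
    mean_baseline = baseline$ua$mean,
    mean_diff = report$ua$mean - baseline$ua$mean,
    mean_diff_se = se,
    variance = report$ua$variance,
    variance_baseline = baseline$ua$variance,
    variance_ratio = report$ua$variance / baseline$ua$variance,
    spread_reduction_pct =
      100 * (1 - report$ua$variance / baseline$ua$variance)
  )
}

#' Write an experiment report to disk
#'
#' Persists the run log as CSV and the summary (uncertainty statistics,
#' sensitivity indices, metadata) as JSON with a fixed schema.
#'
#' @param report An `experiment_report`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_experiment_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$runs, file.path(dir, "runs.csv"),
                   row.names = FALSE)
  summary <- list(
    schema = "fallowsim-report-1",
    name = report$config$name,
    run_count = report$run_count,
    N = report$config$N,
    k = report$sa$k,
    ua = list(mean = report$ua$mean, variance = report$ua$variance,
              quantiles = report$ua$quantiles),
    sa = list(I = report$sa$I, I_se = report$sa$I_se,
              factors = report$sa$factors)
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
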