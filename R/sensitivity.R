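#' Uncertainty summary of a model-output sample
#'
#' Descriptive statistics of a Monte Carlo output distribution: sample mean,
#' unbiased sample variance, interpolated quantiles at the conventional
#' probabilities, and histogram bins.
#'
#' @param outputs Numeric vector of at least two finite model outputs.
#' @param bins Number of histogram bins (default by Sturges' rule).
#' @return A list with `n`, `mean`, `variance`, `sd`, `quantiles` (a tibble
#'   of probability/value pairs at 2.5, 25, 50, 75, 97.5 percent) and
#'   `histogram` (a tibble of bin midpoints and counts).
#' @export
uncertainty_summary <- function(outputs, bins = NULL) {
  outputs <- as.numeric(outputs)
  if (length(outputs) < 2L || any(!is.finite(outputs))) {
    stop("need at least 2 finite outputs", call. = FALSE)
  }
  probs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  qs <- stats::quantile(outputs, probs, type = 7, names = FALSE)
  if (is.null(bins)) bins <- grDevices::nclass.Sturges(outputs)
  h <- graphics::hist(outputs, breaks = bins, plot = FALSE)
  list(
    n = length(outputs),
    mean = mean(outputs),
    variance = stats::var(outputs),
    sd = stats::sd(outputs),
    quantiles = tibble::tibble(prob = probs, value = qs),
    histogram = tibble::tibble(mid = h$mids, count = h$counts)
  )
}

#' Sobol' sensitivity indices from evaluated Saltelli blocks
#'
#' Estimates, for every factor, the first-order index `S` (the fraction of
#' output variance the factor explains on its own) and the total-effect
#' index `ST` (its overall contribution including all interactions), plus
#' the interaction share `I = 1 - sum(S)`.  `V_i` is estimated with the
#' Saltelli (2010) cross-block estimator and the complement variance `VC_i`
#' with the Jansen difference estimator; both radial directions (AB and BA
#' cross blocks) are averaged.  Monte Carlo error bars come from a bootstrap
#' over base-sample indices.
#'
#' Negative estimates (possible at small N) are reported as-is, with a
#' warning when they fall below minus three standard errors — clipping them
#' would mask an insufficient base sample.
#'
#' @param runs A run log from [evaluate_design()] (or anything with
#'   `block`, `base_index`, `output` columns).
#' @param factor_names Optional character vector naming the k factors.
#' @param n_boot Bootstrap resamples for standard errors (default 500).
#' @param boot_seed Seed for the bootstrap resampling only.
#' @return An object of class `sensitivity_result`: list with a `factors`
#'   tibble (`name`, `S`, `ST`, `S_se`, `ST_se`, `S_lo`, `S_hi`, `ST_lo`,
#'   `ST_hi`), the output `mean`, variance `V`, interaction share `I`,
#'   `I_se`, and design metadata `N`, `k`.
#' @export
sobol_indices <- function(runs, factor_names = NULL, n_boot = 500L,
                          boot_seed = 1L) {
  bl <- design_blocks(runs)
  k <- ncol(bl$yAB)
  N <- length(bl$yA)
  if (is.null(factor_names)) factor_names <- paste0("X", seq_len(k))
  stopifnot(length(factor_names) == k)

  V <- stats::var(c(bl$yA, bl$yB))
  if (V <= 0) {
    stop("output variance is zero; sensitivity indices are undefined",
         call. = FALSE)
  }
  est <- .sobol_point_estimate(bl)

  # bootstrap over base-sample indices, jointly across all blocks
  boot_S <- matrix(NA_real_, n_boot, k)
  boot_ST <- matrix(NA_real_, n_boot, k)
  if (n_boot > 0) {
    idx <- .boot_indices(N, n_boot, boot_seed)
    for (b in seq_len(n_boot)) {
      ib <- idx[, b]
      bb <- list(yA = bl$yA[ib], yB = bl$yB[ib],
                 yAB = bl$yAB[ib, , drop = FALSE],
                 yBA = bl$yBA[ib, , drop = FALSE])
      eb <- .sobol_point_estimate(bb)
      boot_S[b, ] <- eb$S
      boot_ST[b, ] <- eb$ST
    }
  }
  S_se <- apply(boot_S, 2, stats::sd)
  ST_se <- apply(boot_ST, 2, stats::sd)
  qs <- function(m, p) apply(m, 2, stats::quantile, probs = p, names = FALSE)

  if (any(est$S < -3 * S_se, na.rm = TRUE)) {
    warning("first-order index estimate below -3*SE; ",
            "the base sample is likely too small", call. = FALSE)
  }

  factors <- tibble::tibble(
    name = factor_names,
    S = est$S, ST = est$ST,
    S_se = S_se, ST_se = ST_se,
    S_lo = qs(boot_S, 0.025), S_hi = qs(boot_S, 0.975),
    ST_lo = qs(boot_ST, 0.025), ST_hi = qs(boot_ST, 0.975)
  )
  I_boot <- 1 - rowSums(boot_S)
  structure(list(
    factors = factors,
    mean = mean(c(bl$yA, bl$yB)),
    V = V,
    I = 1 - sum(est$S),
    I_se = stats::sd(I_boot),
    N = N, k = k
  ), class = "sensitivity_result")
}

# Point estimators on a block list; output is centred first so the
# estimators are exactly invariant to affine rescaling of Y.
.sobol_point_estimate <- function(bl) {
  mu <- mean(c(bl$yA, bl$yB))
  sc <- stats::sd(c(bl$yA, bl$yB))
  if (sc == 0) sc <- 1
  yA <- (bl$yA - mu) / sc
  yB <- (bl$yB - mu) / sc
  yAB <- (bl$yAB - mu) / sc
  yBA <- (bl$yBA - mu) / sc
  V <- stats::var(c(yA, yB))
  k <- ncol(yAB)
  S <- ST <- numeric(k)
  for (i in seq_len(k)) {
    # Saltelli (2010): V_i = E[ y_B * (y_ABi - y_A) ]; both directions
    Vi <- 0.5 * (mean(yB * (yAB[, i] - yA)) + mean(yA * (yBA[, i] - yB)))
    # Jansen: V - VC_i = E[ (y_A - y_ABi)^2 ] / 2; both directions
    VTi <- 0.5 * (mean((yA - yAB[, i])^2) / 2 +
                    mean((yB - yBA[, i])^2) / 2)
    S[i] <- Vi / V
    ST[i] <- VTi / V
  }
  list(S = S, ST = ST)
}

.boot_indices <- function(N, n_boot, boot_seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(boot_seed)
  matrix(sample.int(N, N * n_boot, replace = TRUE), nrow = N)
}

#' Interaction share of output variance
#'
#' The fraction of output variance attributable to factor interactions,
#' `I = 1 - sum(S)`.  Slightly negative values can arise from Monte Carlo
#' noise and are reported as-is (with a warning when below `-tol`).
#'
#' @param S Numeric vector of first-order indices.
#' @param tol Flagging tolerance for negative values (default 0).
#' @return A single number.
#' @examples
#' interaction_share(c(0.5, 0.4))  # 0.1
#' @export
interaction_share <- function(S, tol = 0) {
  I <- 1 - sum(S)
  if (I < -tol) {
    warning("interaction share is negative beyond tolerance (", signif(I, 3),
            "); estimates are likely noisy", call. = FALSE)
  }
  I
}

#' Rank factors by influence and flag negligible ones
#'
#' Orders factors by descending first-order index (ties broken by
#' total-effect index, then name) and flags as negligible every factor whose
#' `S` and `ST` both fall below `threshold` — the candidates for fixing in
#' the exploratory simplification.
#'
#' @param result A `sensitivity_result`.
#' @param threshold Negligibility threshold on both indices (default 0.01).
#' @return The `factors` tibble, ordered, with a logical `negligible`
#'   column and the rank.
#' @export
rank_factors <- function(result, threshold = 0.01) {
  stopifnot(inherits(result, "sensitivity_result"))
  out <- result$factors |>
    dplyr::arrange(dplyr::desc(.data$S), dplyr::desc(.data$ST),
                   .data$name) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      negligible = .data$S < threshold & .data$ST < threshold
    )
  out
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Sobol' sensitivity result: k =", x$k, ", N =", x$N, "\n")
  cat("  output mean", signif(x$mean, 6), ", variance", signif(x$V, 6), "\n")
  cat("  interaction share I =", signif(x$I, 4),
      "(se", signif(x$I_se, 3), ")\n")
  print(x$factors[, c("name", "S", "S_se", "ST", "ST_se")])
  invisible(x)
}

#' Tidy a sensitivity result
#'
#' @param x A `sensitivity_result`.
#' @param ... Unused.
#' @return A tibble with one row per factor and index estimates with
#'   bootstrap standard errors and 95 percent intervals.
#' @export
tidy.sensitivity_result <- function(x, ...) {
  x$factors
}

#' One-row summary of a sensitivity result
#'
#' @inheritParams tidy.sensitivity_result
#' @return A one-row tibble with output mean and variance, the interaction
#'   share and its standard error, and the design size.
#' @export
glance.sensitivity_result <- function(x, ...) {
  tibble::tibble(
    mean = x$mean, variance = x$V,
    sum_S = sum(x$factors$S), interaction = x$I, interaction_se = x$I_se,
    N = x$N, k = x$k, runs = x$N * (2L * x$k + 2L)
  )
}

#' Plot first-order and total-effect indices
#'
#' Dodged bars of `S` and `ST` per factor with bootstrap 95 percent
#' intervals — a linear rendering of the classical index pie charts.
#'
#' @param object A `sensitivity_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  d <- object$factors |>
    tidyr::pivot_longer(cols = c("S", "ST"), names_to = "index",
                        values_to = "value") |>
    dplyr::mutate(
      lo = ifelse(.data$index == "S", .data$S_lo, .data$ST_lo),
      hi = ifelse(.data$index == "S", .data$S_hi, .data$ST_hi)
    )
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$name,
                                                     -.data$value),
                                  y = .data$value, fill = .data$index)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "variance share",
                  fill = NULL,
                  title = "Sobol' sensitivity indices") +
    ggplot2::theme_minimal()
}

#' Write a sensitivity report to CSV and JSON
#'
#' @param result A `sensitivity_result`.
#' @param stem Output path stem; `<stem>.csv` gets the per-factor table and
#'   `<stem>.json` the full report.
#' @return The two paths, invisibly.
#' @export
write_sensitivity_report <- function(result, stem) {
  csv <- paste0(stem, ".csv")
  js <- paste0(stem, ".json")
  utils::write.csv(result$factors, csv, row.names = FALSE)
  jsonlite::write_json(
    list(mean = result$mean, V = result$V, I = result$I,
         I_se = result$I_se, N = result$N, k = result$k,
         factors = result$factors),
    js, auto_unbox = TRUE, digits = NA
  )
  invisible(c(csv, js))
}
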