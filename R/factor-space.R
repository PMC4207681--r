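#' The nine uncertain factors of the enrollment model
#'
#' Builds the default factor space: one row per uncertain input of the
#' simulator, with its probability distribution.  Three farmer-level
#' demographic factors (RETIREMENT, PRODUCTION, TENURE) carry empirical
#' discrete PDFs; the remaining six are institutional or behavioural factors
#' with uniform distributions over their supports.
#'
#' Kinds:
#' \describe{
#'   \item{discrete-weighted}{ordered support values with explicit masses}
#'   \item{discrete-uniform-range}{equiprobable ordered numeric grid}
#'   \item{continuous-uniform}{uniform on the interval `(lo, hi]`}
#'   \item{categorical}{equiprobable indexed alternatives in a fixed,
#'     documented order (OWA rules by descending orness; EBI layers by
#'     construction index)}
#' }
#'
#' @return A tibble with columns `name`, `kind`, `support` (list of numeric
#'   vectors; for continuous kinds the `(lo, hi]` bounds), `prob` (list of
#'   mass vectors; uniform kinds carry equal masses), and `fixed` (`NA` for a
#'   free factor, otherwise the value the factor is pinned to).
#' @examples
#' crp_factors()
#' @export
crp_factors <- function() {
  spec <- list(
    list("RETIREMENT", "discrete-weighted", c(0, 1), c(.06, .94)),
    list("PRODUCTION", "discrete-weighted", c(0, .2, .4, .6, .8, 1),
         c(0, .06, .06, .11, .15, .62)),
    list("TENURE", "discrete-weighted", c(0, .2, .4, .6, .8, 1),
         c(.04, .14, .18, .14, .15, .35)),
    list("DE", "discrete-uniform-range", seq(0.5, 1.5, by = 0.1), NULL),
    list("OWA", "categorical", 0:16, NULL),
    list("LAND", "continuous-uniform", c(0, 1), NULL),
    list("BID", "discrete-uniform-range", seq(0, 0.16, by = 0.01), NULL),
    list("EBI", "categorical", 1:6, NULL),
    list("n", "discrete-uniform-range", 18:28, NULL)
  )
  space <- tibble::tibble(
    name = vapply(spec, `[[`, "", 1L),
    kind = vapply(spec, `[[`, "", 2L),
    support = lapply(spec, function(s) as.numeric(s[[3]])),
    prob = lapply(spec, function(s) {
      if (!is.null(s[[4]])) return(as.numeric(s[[4]]))
      if (s[[2]] == "continuous-uniform") return(NULL)
      rep(1 / length(s[[3]]), length(s[[3]]))
    }),
    fixed = NA_real_
  )
  validate_factor_space(space)
  space
}

#' Validate a factor-space tibble
#'
#' Checks the structural invariants: masses non-negative and summing to one,
#' strictly increasing supports for ordered kinds, and any fixed value lying
#' in its factor's support.
#'
#' @param space A factor-space tibble as produced by [crp_factors()].
#' @return `space`, invisibly, or an error.
#' @export
validate_factor_space <- function(space) {
  stopifnot(is.data.frame(space),
            all(c("name", "kind", "support", "prob", "fixed") %in%
                  names(space)))
  if (anyDuplicated(space$name)) {
    stop("factor names must be unique", call. = FALSE)
  }
  for (i in seq_len(nrow(space))) {
    nm <- space$name[i]
    kind <- space$kind[i]
    sup <- space$support[[i]]
    pr <- space$prob[[i]]
    if (!kind %in% c("discrete-weighted", "discrete-uniform-range",
                     "continuous-uniform", "categorical")) {
      stop("unknown kind for factor ", nm, call. = FALSE)
    }
    if (kind == "continuous-uniform") {
      if (length(sup) != 2L || sup[1] >= sup[2]) {
        stop("continuous factor ", nm, " needs (lo, hi] bounds",
             call. = FALSE)
      }
    } else {
      if (is.unsorted(sup, strictly = TRUE)) {
        stop("support of ", nm, " must be strictly increasing",
             call. = FALSE)
      }
      if (is.null(pr) || length(pr) != length(sup) || any(pr < 0) ||
          abs(sum(pr) - 1) > 1e-12) {
        stop("masses of ", nm, " must be non-negative and sum to 1",
             call. = FALSE)
      }
    }
    fx <- space$fixed[i]
    if (!is.na(fx) && !.in_support(kind, sup, fx)) {
      stop("fixed value of ", nm, " lies outside its support",
           call. = FALSE)
    }
  }
  invisible(space)
}

.in_support <- function(kind, sup, value) {
  if (kind == "continuous-uniform") {
    value > sup[1] && value <= sup[2]
  } else {
    any(abs(sup - value) < 1e-9)
  }
}

#' Inverse-CDF transform of one factor
#'
#' Maps unit-interval coordinates to factor values.  Discrete kinds use
#' right-open cumulative intervals: `u` in `[0, p1)` maps to the first
#' support value, `[p1, p1 + p2)` to the second, and so on, so the boundary
#' coordinate belongs to the next value.  The continuous-uniform kind maps
#' `u` to `lo + u * (hi - lo)`, with `u = 0` nudged to
#' `lo + 1e-12 * (hi - lo)` so the open lower bound is respected.
#'
#' @param space A factor-space tibble.
#' @param name Name of the factor to transform.
#' @param u Numeric vector of coordinates in `[0, 1)`.
#' @return Numeric vector of factor values, one per coordinate.
#' @examples
#' sp <- crp_factors()
#' inverse_cdf(sp, "RETIREMENT", c(0.05, 0.06))  # -> 0, 1
#' @export
inverse_cdf <- function(space, name, u) {
  i <- .factor_index(space, name)
  if (!is.na(space$fixed[i])) {
    stop("factor ", name, " is fixed; sampling it is a misuse",
         call. = FALSE)
  }
  if (any(u < 0 | u >= 1)) {
    stop("`u` must lie in [0, 1)", call. = FALSE)
  }
  .inverse_cdf_spec(space$kind[i], space$support[[i]], space$prob[[i]], u)
}

.inverse_cdf_spec <- function(kind, sup, prob, u) {
  if (kind == "continuous-uniform") {
    lo <- sup[1]; hi <- sup[2]
    u <- ifelse(u == 0, 1e-12, u)
    return(lo + u * (hi - lo))
  }
  cum <- cumsum(prob)
  cum[length(cum)] <- 1  # guard rounding of the final mass
  # first index whose cumulative mass strictly exceeds u (right-open cells)
  idx <- findInterval(u, cum) + 1L
  idx[idx > length(sup)] <- length(sup)
  sup[idx]
}

.factor_index <- function(space, name) {
  i <- match(name, space$name)
  if (is.na(i)) stop("unknown factor: ", name, call. = FALSE)
  i
}

#' Fix a factor at a constant value
#'
#' Marks the named factor as fixed, removing it from the free design columns
#' while every transform of a design injects the constant.
#'
#' @param space A factor-space tibble.
#' @param name Factor to fix.
#' @param value Value in the factor's support.
#' @return The updated factor-space tibble.
#' @examples
#' fix_factor(crp_factors(), "n", 23)
#' @export
fix_factor <- function(space, name, value) {
  i <- .factor_index(space, name)
  if (!.in_support(space$kind[i], space$support[[i]], value)) {
    stop("value ", value, " is outside the support of ", name,
         call. = FALSE)
  }
  space$fixed[i] <- value
  space
}

#' Names of the free (non-fixed) factors, in factor-space order
#' @param space A factor-space tibble.
#' @return Character vector.
#' @export
free_factors <- function(space) {
  space$name[is.na(space$fixed)]
}

#' Distribution median and mean of a factor
#'
#' The median of a discrete factor is the smallest support value whose
#' cumulative mass reaches 0.5; for a continuous-uniform factor it is the
#' interval midpoint.  The mean is the mass-weighted support average
#' (interval midpoint for continuous factors).  Used when fixing negligible
#' factors for the exploratory simplification.
#'
#' @param space A factor-space tibble.
#' @param name Factor name.
#' @return A single numeric value.
#' @export
factor_median <- function(space, name) {
  i <- .factor_index(space, name)
  sup <- space$support[[i]]
  if (space$kind[i] == "continuous-uniform") {
    return(mean(sup))
  }
  cum <- cumsum(space$prob[[i]])
  sup[which(cum >= 0.5 - 1e-12)[1]]
}

#' @rdname factor_median
#' @export
factor_mean <- function(space, name) {
  i <- .factor_index(space, name)
  sup <- space$support[[i]]
  if (space$kind[i] == "continuous-uniform") {
    return(mean(sup))
  }
  sum(sup * space$prob[[i]])
}

#' Midpoint of a factor's support
#'
#' The middle element of the ordered support for discrete kinds (the median
#' of the support list, not of the distribution), or the interval midpoint
#' for a continuous factor.  This is the constant used when fixing the
#' dominant factor for the explanatory simplification.
#'
#' @inheritParams factor_median
#' @return A single numeric value.
#' @examples
#' support_midpoint(crp_factors(), "n")  # 23
#' @export
support_midpoint <- function(space, name) {
  i <- .factor_index(space, name)
  sup <- space$support[[i]]
  if (space$kind[i] == "continuous-uniform") {
    return(mean(sup))
  }
  # middle element of the ordered support (lower middle for even lengths,
  # so the result always lies in the support)
  sup[ceiling(length(sup) / 2)]
}

# Mid-quantile of a support value: the centre of its cumulative-mass cell.
# Used so that fixing a farmer-level demographic factor pins the population
# quantile shift without collapsing agent heterogeneity.
.factor_mid_quantile <- function(space, name) {
  i <- .factor_index(space, name)
  stopifnot(!is.na(space$fixed[i]))
  sup <- space$support[[i]]
  if (space$kind[i] == "continuous-uniform") {
    return((space$fixed[i] - sup[1]) / (sup[2] - sup[1]))
  }
  pr <- space$prob[[i]]
  j <- which(abs(sup - space$fixed[i]) < 1e-9)[1]
  cum <- c(0, cumsum(pr))
  (cum[j] + cum[j + 1L]) / 2
}

#' Transform design coordinates into complete factor rows
#'
#' Maps each row of a unit-hypercube design (columns ordered as the free
#' factors of `space`) to a complete nine-factor input for the simulator.
#' Free factors are transformed through their inverse CDFs; fixed factors are
#' injected as constants.  The raw coordinate `u` of every factor is
#' retained alongside its value: farmer-level demographic factors enter the
#' simulator as population quantile shifts, for which the coordinate, not the
#' transformed value, is the operative quantity (fixed factors carry the
#' mid-quantile of their pinned value).
#'
#' @param space A factor-space tibble.
#' @param u A numeric matrix (rows = design points, columns = free factors)
#'   or a single vector of length `length(free_factors(space))`.
#' @return A tibble with one row per design point and, per factor `F`,
#'   columns `F` (value) and `u_F` (coordinate).
#' @export
transform_design <- function(space, u) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1L)
  free <- free_factors(space)
  if (ncol(u) != length(free)) {
    stop("design has ", ncol(u), " columns but ", length(free),
         " factors are free", call. = FALSE)
  }
  out <- vector("list", 2L * nrow(space))
  nms <- character(2L * nrow(space))
  for (i in seq_len(nrow(space))) {
    nm <- space$name[i]
    if (is.na(space$fixed[i])) {
      uu <- u[, match(nm, free)]
      val <- inverse_cdf(space, nm, uu)
    } else {
      uu <- rep(.factor_mid_quantile(space, nm), nrow(u))
      val <- rep(space$fixed[i], nrow(u))
    }
    out[[2L * i - 1L]] <- val
    out[[2L * i]] <- uu
    nms[2L * i - 1L] <- nm
    nms[2L * i] <- paste0("u_", nm)
  }
  names(out) <- nms
  tibble::as_tibble(out)
}

#' Read or write a factor space as YAML
#'
#' Serialises the factor-space tibble to a YAML document (one entry per
#' factor: name, kind, support, probabilities, fixed value) and back.
#'
#' @param space A factor-space tibble.
#' @param path File path.
#' @return `write_factor_space` returns `path` invisibly;
#'   `read_factor_space` returns the factor-space tibble.
#' @export
write_factor_space <- function(space, path) {
  doc <- lapply(seq_len(nrow(space)), function(i) {
    e <- list(name = space$name[i], kind = space$kind[i],
              support = as.numeric(space$support[[i]]))
    # equiprobable kinds reconstruct their masses on read; writing them
    # would only lose precision in the decimal rendering
    if (space$kind[i] == "discrete-weighted") {
      e$probabilities <- space$prob[[i]]
    }
    if (!is.na(space$fixed[i])) e$fixed_value <- space$fixed[i]
    e
  })
  yaml::write_yaml(list(factors = doc), path)
  invisible(path)
}

#' @rdname write_factor_space
#' @export
read_factor_space <- function(path) {
  doc <- yaml::read_yaml(path)
  entries <- doc$factors
  space <- tibble::tibble(
    name = vapply(entries, `[[`, "", "name"),
    kind = vapply(entries, `[[`, "", "kind"),
    support = lapply(entries, function(e) as.numeric(e$support)),
    prob = lapply(entries, function(e) {
      if (!is.null(e$probabilities)) return(as.numeric(e$probabilities))
      if (e$kind == "continuous-uniform") return(NULL)
      rep(1 / length(e$support), length(e$support))
    }),
    fixed = vapply(entries, function(e) {
      if (is.null(e$fixed_value)) NA_real_ else as.numeric(e$fixed_value)
    }, 0)
  )
  validate_factor_space(space)
  space
}
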