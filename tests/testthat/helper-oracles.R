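# Shared fixtures and independent oracles used across the suite.

.fixtures <- new.env(parent = emptyenv())

# Small landscape for fast ABM unit tests.
small_landscape <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- generate_landscape(
      landscape_config(nrow = 80L, ncol = 80L, n_parcels = 400L), seed = 11L)
  }
  .fixtures$small
}

small_context <- function() {
  if (is.null(.fixtures$small_ctx)) {
    .fixtures$small_ctx <- landscape_context(small_landscape())
  }
  .fixtures$small_ctx
}

# Default desk landscape (200x200, full parcel complement), shared by the
# acceptance-level tests.
desk_context <- function() {
  if (is.null(.fixtures$desk_ctx)) {
    .fixtures$desk_ctx <- landscape_context(
      generate_landscape(landscape_config(), seed = 7L))
  }
  .fixtures$desk_ctx
}

# Sobol' g-function and its closed-form indices.
g_function <- function(U, a) {
  out <- rep(1, nrow(U))
  for (i in seq_along(a)) {
    out <- out * (abs(4 * U[, i] - 2) + a[i]) / (1 + a[i])
  }
  out
}

g_function_indices <- function(a) {
  Vi <- (1 / 3) / (1 + a)^2
  V <- prod(1 + Vi) - 1
  list(S = Vi / V,
       ST = vapply(seq_along(a),
                   function(i) Vi[i] * prod(1 + Vi[-i]), 0) / V)
}

# Ishigami function on U(0,1)^3 inputs (rescaled internally to (-pi,pi))
# and its closed-form indices.
ishigami <- function(U, a = 7, b = 0.1) {
  X <- -pi + 2 * pi * U
  sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1])
}

ishigami_indices <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- 8 * b^2 * pi^8 / 225
  V <- V1 + V2 + V13
  list(S = c(V1, V2, 0) / V, ST = c(V1 + V13, V2, V13) / V)
}

# Exhaustive double-loop enumeration of first-order and total-effect
# indices for a model over independent discrete factors with equiprobable
# levels. Independent of the Saltelli estimator path.
enumerate_indices <- function(f, levels_list) {
  grid <- expand.grid(levels_list, KEEP.OUT.ATTRS = FALSE)
  y <- apply(as.matrix(grid), 1, f)
  V <- mean(y^2) - mean(y)^2
  k <- length(levels_list)
  S <- ST <- numeric(k)
  for (i in seq_len(k)) {
    cond_mean <- tapply(y, grid[[i]], mean)
    S[i] <- (mean(cond_mean^2) - mean(cond_mean)^2) / V
    others <- interaction(grid[, -i, drop = FALSE], drop = TRUE)
    within_var <- tapply(y, others, function(v) mean(v^2) - mean(v)^2)
    ST[i] <- mean(within_var) / V
  }
  list(S = S, ST = ST, V = V)
}

# Brute-force Euclidean distance transform (reference for the two-pass
# algorithm).
brute_edt <- function(mask, cell_size = 1) {
  nr <- nrow(mask); nc <- ncol(mask)
  tr <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i, j] <- sqrt(min((tr[, 1] - i)^2 + (tr[, 2] - j)^2))
    }
  }
  out * cell_size
}

# Evaluate a discrete-factor model over a Saltelli design by mapping
# unit-interval coordinates to equiprobable levels.
discrete_model_on_design <- function(f, levels_list, N) {
  k <- length(levels_list)
  design <- saltelli_design(k, N)
  to_level <- function(u, lv) lv[pmin(floor(u * length(lv)) + 1L,
                                      length(lv))]
  model <- function(U) {
    X <- vapply(seq_len(k),
                function(i) to_level(U[, i], levels_list[[i]]),
                numeric(nrow(U)))
    apply(X, 1, f)
  }
  evaluate_design(design, model, vectorized = TRUE)
}
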