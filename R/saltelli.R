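#' Saltelli block design for variance-based sensitivity analysis
#'
#' Builds the radial block design whose model evaluations yield both the
#' first-order and total-effect Sobol' indices for all `k` free factors.
#' Matrices A and B are taken from a single `2k`-dimensional Sobol' stream
#' (columns `1..k` form A, columns `k+1..2k` form B) and, for every factor
#' `i`, the cross matrices `AB_i` (A with column `i` replaced from B) and
#' `BA_i` (B with column `i` replaced from A) are formed.  Total size is
#' `N * (2k + 2)` rows, the scheme used by the SimLab-style estimators.
#'
#' @param k Number of free factors (>= 1).
#' @param N Base sample size (>= 2).  The default of 128 reproduces the
#'   canonical run counts 2560 / 1536 / 2304 at k = 9 / 5 / 8.
#' @return An object of class `saltelli_design`: a list with `k`, `N`, and
#'   `rows`, a tibble with columns `row_id`, `block` (`"A"`, `"B"`,
#'   `"AB<i>"`, `"BA<i>"`), `base_index` (1..N within each block) and the
#'   coordinate columns `u1..uk`.
#' @examples
#' d <- saltelli_design(3, 8)
#' nrow(d$rows)  # 8 * (2*3 + 2) = 64
#' @export
saltelli_design <- function(k, N = 128L) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != floor(N)) {
    stop("`N` must be an integer >= 2", call. = FALSE)
  }
  k <- as.integer(k); N <- as.integer(N)
  # skip the zero point and the all-centre point: the latter would make the
  # first rows of A and B coincide, which the radial estimators assume away
  base <- sobol_sequence(2L * k, N, skip = 2L)
  A <- base[, seq_len(k), drop = FALSE]
  B <- base[, k + seq_len(k), drop = FALSE]
  blocks <- vector("list", 2L * k + 2L)
  labels <- character(2L * k + 2L)
  blocks[[1L]] <- A; labels[1L] <- "A"
  blocks[[2L]] <- B; labels[2L] <- "B"
  for (i in seq_len(k)) {
    AB <- A; AB[, i] <- B[, i]
    BA <- B; BA[, i] <- A[, i]
    blocks[[2L + i]] <- AB; labels[2L + i] <- paste0("AB", i)
    blocks[[2L + k + i]] <- BA; labels[2L + k + i] <- paste0("BA", i)
  }
  u <- do.call(rbind, blocks)
  colnames(u) <- paste0("u", seq_len(k))
  rows <- tibble::tibble(
    row_id = seq_len(nrow(u)),
    block = rep(labels, each = N),
    base_index = rep(seq_len(N), times = length(labels))
  )
  rows <- dplyr::bind_cols(rows, tibble::as_tibble(u))
  structure(list(k = k, N = N, rows = rows), class = "saltelli_design")
}

#' @export
print.saltelli_design <- function(x, ...) {
  cat("Saltelli design: k =", x$k, ", N =", x$N, ",",
      nrow(x$rows), "rows (N*(2k+2))\n")
  invisible(x)
}

#' Evaluate a model over a Saltelli design
#'
#' Runs a deterministic scalar model on every design row and returns the run
#' log with outputs aligned to blocks and base-sample indices.  The model
#' must be a pure function of the coordinate vector: identical rows must
#' yield identical outputs, otherwise the block estimators are biased.
#'
#' Evaluation can be checkpointed: with `checkpoint` set, finished rows are
#' appended to a CSV keyed by a design hash, and a re-run resumes after the
#' last completed row (aborting if the checkpoint belongs to a different
#' design).
#'
#' @param design A `saltelli_design`.
#' @param model A function.  With `vectorized = FALSE` (default) it receives
#'   one numeric coordinate vector of length `k` and returns a scalar; with
#'   `vectorized = TRUE` it receives the full coordinate matrix and returns a
#'   vector of outputs.
#' @param checkpoint Optional path to a checkpoint CSV.
#' @param vectorized Whether `model` accepts the whole matrix at once.
#' @return The design's `rows` tibble with an `output` column appended.
#' @export
evaluate_design <- function(design, model, checkpoint = NULL,
                            vectorized = FALSE) {
  stopifnot(inherits(design, "saltelli_design"))
  rows <- design$rows
  ucols <- paste0("u", seq_len(design$k))
  u <- as.matrix(rows[, ucols])
  n <- nrow(u)
  out <- rep(NA_real_, n)
  start <- 1L
  dhash <- .design_hash(design)

  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    prev <- utils::read.csv(checkpoint)
    if (nrow(prev) > 0) {
      if (!identical(unique(prev$design_hash), dhash)) {
        stop("checkpoint belongs to a different design; refusing to resume",
             call. = FALSE)
      }
      done <- prev$row_id
      out[done] <- prev$output
      start <- max(done) + 1L
    }
  }

  if (start <= n) {
    if (vectorized) {
      out[start:n] <- model(u[start:n, , drop = FALSE])
      .append_checkpoint(checkpoint, dhash, start:n, out[start:n])
    } else {
      chunk <- integer(0)
      for (i in start:n) {
        out[i] <- model(u[i, ])
        chunk <- c(chunk, i)
        if (!is.null(checkpoint) && length(chunk) >= 64L) {
          .append_checkpoint(checkpoint, dhash, chunk, out[chunk])
          chunk <- integer(0)
        }
      }
      .append_checkpoint(checkpoint, dhash, chunk, out[chunk])
    }
  }

  bad <- which(!is.finite(out))
  if (length(bad) > 0) {
    stop("model returned non-finite output at design row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)
  }
  rows$output <- out
  rows
}

.append_checkpoint <- function(checkpoint, dhash, ids, outputs) {
  if (is.null(checkpoint) || length(ids) == 0L) return(invisible(NULL))
  df <- data.frame(design_hash = dhash, row_id = ids, output = outputs)
  utils::write.table(df, checkpoint, sep = ",", row.names = FALSE,
                     col.names = !file.exists(checkpoint), append =
                       file.exists(checkpoint))
  invisible(NULL)
}

# Cheap deterministic fingerprint of a design (dims plus a coordinate digest)
.design_hash <- function(design) {
  u <- as.matrix(design$rows[, paste0("u", seq_len(design$k))])
  s <- sum(u * seq_len(length(u))) %% 1e9
  paste0("k", design$k, "N", design$N, "s", format(s, digits = 15))
}

#' Split an evaluated design into estimator blocks
#'
#' Reshapes a run log from [evaluate_design()] into the per-block output
#' arrays consumed by the index estimators.
#'
#' @param runs Tibble with `block`, `base_index`, `output` columns.
#' @return A list with `yA`, `yB` (length-N vectors) and `yAB`, `yBA`
#'   (N x k matrices).
#' @keywords internal
#' @export
design_blocks <- function(runs) {
  labs <- unique(runs$block)
  k <- sum(startsWith(labs, "AB"))
  stopifnot(k >= 1, all(c("A", "B") %in% labs))
  get <- function(lab) {
    b <- runs[runs$block == lab, ]
    b$output[order(b$base_index)]
  }
  yA <- get("A")
  yB <- get("B")
  yAB <- vapply(seq_len(k), function(i) get(paste0("AB", i)), yA)
  yBA <- vapply(seq_len(k), function(i) get(paste0("BA", i)), yA)
  list(yA = yA, yB = yB, yAB = yAB, yBA = yBA)
}
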