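#' Sobol' low-discrepancy sequences
#'
#' Generates successive points of the Sobol' sequence, the quasi-random
#' sequence used to build Saltelli sampling designs.  Direction numbers are
#' initialised from the published Joe & Kuo (2008) table of primitive
#' polynomials and initial values, which supports up to 32 dimensions here.
#' The all-zeros first element of the sequence is skipped by default so that
#' the first returned point is (0.5, ..., 0.5).
#'
#' @param dim Dimension of the points, an integer in 1..32.
#' @param count Number of points to return.
#' @param skip Number of leading sequence elements to drop.  The default of 1
#'   drops only the degenerate all-zeros point.
#'
#' @return A `count` x `dim` numeric matrix with all entries in `[0, 1)`.
#'   Deterministic: the same `(dim, count, skip)` always yields the same
#'   matrix.
#'
#' @references Joe, S. and Kuo, F.Y. (2008) Constructing Sobol sequences with
#'   better two-dimensional projections. SIAM J. Sci. Comput. 30(5).
#' @examples
#' sobol_sequence(2, 4)
#' @export
sobol_sequence <- function(dim, count, skip = 1L) {
  if (!is.numeric(dim) || length(dim) != 1L || dim < 1 || dim > 32 ||
      dim != floor(dim)) {
    stop("`dim` must be a single integer in 1..32", call. = FALSE)
  }
  if (!is.numeric(count) || length(count) != 1L || count < 1 ||
      count != floor(count)) {
    stop("`count` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(skip) || length(skip) != 1L || skip < 0 ||
      skip != floor(skip)) {
    stop("`skip` must be a non-negative integer", call. = FALSE)
  }
  dim <- as.integer(dim)
  count <- as.integer(count)
  skip <- as.integer(skip)
  nbits <- 30L
  total <- count + skip
  if (total >= 2^nbits) {
    stop("requested more points than the generator's period supports",
         call. = FALSE)
  }

  v <- .sobol_direction_vectors(dim, nbits)   # dim x nbits integer matrix

  # Antonov-Saleev Gray-code update: element i flips the direction vector
  # indexed by the rightmost zero bit of (i - 1); element 0 is all zeros.
  pts <- matrix(0L, nrow = total, ncol = dim)
  x <- integer(dim)
  for (i in seq_len(total - 1L)) {
    c_idx <- .rightmost_zero_bit(i - 1L)
    x <- bitwXor(x, v[, c_idx])
    pts[i + 1L, ] <- x
  }
  pts[(skip + 1L):total, , drop = FALSE] / 2^nbits
}

# 1-based index of the rightmost zero bit of a non-negative integer
.rightmost_zero_bit <- function(n) {
  c_idx <- 1L
  while (bitwAnd(n, 1L) == 1L) {
    n <- bitwShiftR(n, 1L)
    c_idx <- c_idx + 1L
  }
  c_idx
}

# Direction vectors v_j (as integers scaled by 2^nbits) for each dimension.
# Cached per (dim, nbits) since the table parse and recurrences are reusable.
.sobol_cache <- new.env(parent = emptyenv())

.sobol_direction_vectors <- function(dim, nbits) {
  key <- paste0("d", dim, "b", nbits)
  if (!is.null(.sobol_cache[[key]])) {
    return(.sobol_cache[[key]])
  }
  tab <- .joe_kuo_table()
  v <- matrix(0L, nrow = dim, ncol = nbits)
  # dimension 1: van der Corput in base 2, v_j = 2^(nbits - j)
  v[1L, ] <- bitwShiftL(1L, nbits - seq_len(nbits))
  if (dim > 1L) {
    for (d in 2:dim) {
      entry <- tab[[d - 1L]]
      s <- entry$degree
      poly <- entry$poly
      m <- entry$m
      vd <- integer(nbits)
      for (j in seq_len(min(s, nbits))) {
        vd[j] <- bitwShiftL(m[j], nbits - j)
      }
      if (nbits > s) {
        for (j in (s + 1L):nbits) {
          newv <- bitwXor(vd[j - s], bitwShiftR(vd[j - s], s))
          for (k in seq_len(s - 1L)) {
            # coefficient of x^(s-k) in the primitive polynomial
            if (bitwAnd(bitwShiftR(poly, s - k), 1L) == 1L) {
              newv <- bitwXor(newv, vd[j - k])
            }
          }
          vd[j] <- newv
        }
      }
      v[d, ] <- vd
    }
  }
  .sobol_cache[[key]] <- v
  v
}

# Parse the Joe-Kuo initialisation table shipped with the package.
.joe_kuo_table <- function() {
  if (!is.null(.sobol_cache[["joe_kuo"]])) {
    return(.sobol_cache[["joe_kuo"]])
  }
  path <- system.file("extdata", "joe-kuo-directions.txt",
                      package = "fallowsim", mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  tab <- lapply(lines, function(ln) {
    xs <- as.integer(strsplit(trimws(ln), "\\s+")[[1]])
    list(dim = xs[1], degree = xs[2], poly = xs[3], m = xs[-(1:3)])
  })
  stopifnot(vapply(tab, function(e) e$dim, 0L) == seq_len(length(tab)) + 1L)
  .sobol_cache[["joe_kuo"]] <- tab
  tab
}

#' Star-discrepancy proxy for a point set
#'
#' Computes the L-infinity star discrepancy of a point set exactly in one
#' dimension and by evaluating the local discrepancy over the grid of points
#' (the classical lower-bound construction, exact for axis-aligned anchored
#' boxes with corners at the points) in two dimensions.  Used to verify that
#' the Sobol' sequence is more uniform than pseudo-random sampling.
#'
#' @param pts A numeric matrix of points in `[0, 1)^d` with d in 1..2.
#' @return The star discrepancy (a number in `[0, 1]`).
#' @keywords internal
#' @export
star_discrepancy <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  d <- ncol(pts)
  if (d == 1L) {
    x <- sort(pts[, 1])
    i <- seq_len(n)
    return(max(abs(x - (i - 1) / n), abs(x - i / n)))
  }
  if (d != 2L) {
    stop("star_discrepancy supports 1 or 2 dimensions", call. = FALSE)
  }
  px <- pts[, 1]; py <- pts[, 2]
  xs <- sort(unique(c(px, 1)))
  ys <- sort(unique(c(py, 1)))
  ord <- order(px)
  px_s <- px[ord]; py_s <- py[ord]
  worst <- 0
  for (x in xs) {
    open_y <- sort(py_s[seq_len(findInterval(x, px_s, left.open = TRUE))])
    closed_y <- sort(py_s[seq_len(findInterval(x, px_s))])
    # counts of points strictly inside / inside-closure of [0,x] x [0,y]
    open_cnt <- findInterval(ys, open_y, left.open = TRUE) / n
    closed_cnt <- findInterval(ys, closed_y) / n
    vol <- x * ys
    worst <- max(worst, abs(vol - open_cnt), abs(closed_cnt - vol))
  }
  worst
}
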