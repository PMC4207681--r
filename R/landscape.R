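#' Land-use codes used by the simulator
#'
#' @return A named integer vector mapping class names (`CROP`, `PASTURE`,
#'   `FOREST`, `WATER`, `OTHER`, `FALLOW`) to raster codes.
#' @export
landuse_codes <- function() {
  c(CROP = 1L, PASTURE = 2L, FOREST = 3L, WATER = 4L, OTHER = 5L,
    FALLOW = 6L)
}

#' Configuration for the synthetic landscape generator
#'
#' The desk-scale default (200 x 200 cells at 30 m, ~300 parcels) keeps a
#' full analysis run in seconds; the `"study-area"` profile reproduces the
#' structural scale of the case-study region (about 985 km^2 at 30 m
#' resolution with 2687 farmland parcels).
#'
#' Both profiles carry the full complement of 2687 farmland parcels: the
#' ratio of decision-making agents to the agency's annual acceptance cap is
#' the structural feature that places the system in the budget-limited
#' regime, so the desk profile shrinks parcel extents, not the agent
#' population.
#'
#' @param nrow,ncol Grid dimensions in cells.
#' @param cell_size Cell edge length in metres.
#' @param n_parcels Number of farmland parcels.
#' @param proportions Named numeric vector of target land-use shares over
#'   `crop`, `pasture`, `forest`, `water`, `other`; must sum to 1.
#' @param smoothing Gaussian smoothing radius of the latent random fields,
#'   in cells.
#' @param cash_rent County cash-rent constant in dollars per acre per year;
#'   soil rental rates are a productivity index (0.6-1.5) times this.
#' @param ebi_shared Fraction of variance shared by all benefit layers
#'   through a common latent field; controls the positive correlation of
#'   the six composite EBI surfaces.
#' @param ebi_cor_band Target band for the pairwise Pearson correlations of
#'   the EBI surfaces (a config target, not a hard guarantee).
#' @param profile Either `"desk"` (default) or `"study-area"`.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(nrow = 200L, ncol = 200L, cell_size = 30,
                             n_parcels = 2687L,
                             proportions = c(crop = 0.45, pasture = 0.20,
                                             forest = 0.20, water = 0.05,
                                             other = 0.10),
                             smoothing = 3, cash_rent = 110,
                             ebi_shared = 0.2,
                             ebi_cor_band = c(0.35, 0.89),
                             profile = c("desk", "study-area")) {
  profile <- match.arg(profile)
  if (profile == "study-area") {
    nrow <- 1046L; ncol <- 1046L; n_parcels <- 2687L
  }
  stopifnot(abs(sum(proportions) - 1) < 1e-9, all(proportions >= 0),
            all(c("crop", "pasture", "forest", "water", "other") %in%
                  names(proportions)))
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cell_size = cell_size, n_parcels = as.integer(n_parcels),
                 proportions = proportions, smoothing = smoothing,
                 cash_rent = cash_rent, ebi_shared = ebi_shared,
                 ebi_cor_band = ebi_cor_band, profile = profile),
            class = "landscape_config")
}

#' Generate a synthetic landscape bundle
#'
#' Builds a seeded, fully deterministic landscape: contiguous water and
#' forest patches cut from smoothed random fields, the remaining area
#' tessellated into farmland parcels (nearest-seed Voronoi regions), per-
#' parcel crop/pasture assignment with a per-cell sprinkle of other
#' non-eligible use, a slope surface, exact Euclidean distance surfaces to
#' water and forest, a soil-rental-rate surface, and six positively
#' correlated composite environmental-benefit (EBI) surfaces rescaled into
#' [50, 350] points.  Each EBI surface is the weighted sum of one of three
#' N1 variants, one of two N2 variants, and the single N3 layer.
#'
#' @param config A [landscape_config()].
#' @param seed Integer seed; the same `(config, seed)` pair always yields a
#'   bit-identical bundle.
#' @return An object of class `crp_landscape`: a list of co-registered
#'   matrices (`landuse`, `parcel_id`, `slope`, `dist_water`,
#'   `dist_forest`, `srr`), a list `ebi` of six matrices, plus `cell_size`
#'   and the `config`.
#' @export
generate_landscape <- function(config = landscape_config(), seed = 1L) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$nrow; nc <- config$ncol
  ncell <- nr * nc
  if (config$n_parcels > ncell) {
    stop("parcel count exceeds cell count", call. = FALSE)
  }
  codes <- landuse_codes()
  p <- config$proportions

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed))

  sm <- config$smoothing
  f_water <- .smooth_field(nr, nc, sm * 2)   # broader patches for water
  f_forest <- .smooth_field(nr, nc, sm * 2)
  f_slope <- .smooth_field(nr, nc, sm)
  f_prod <- .smooth_field(nr, nc, sm)

  landuse <- matrix(codes[["CROP"]], nr, nc)
  n_water <- round(p[["water"]] * ncell)
  if (n_water > 0) {
    thr <- sort(f_water)[n_water]
    landuse[f_water <= thr] <- codes[["WATER"]]
  }
  n_forest <- round(p[["forest"]] * ncell)
  if (n_forest > 0) {
    avail <- which(landuse != codes[["WATER"]])
    ord <- avail[order(f_forest[avail])]
    landuse[ord[seq_len(min(n_forest, length(ord)))]] <- codes[["FOREST"]]
  }

  farm_cells <- which(landuse == codes[["CROP"]])
  if (config$n_parcels > length(farm_cells)) {
    stop("parcel count exceeds available farmland cells", call. = FALSE)
  }
  seeds <- sort(sample(farm_cells, config$n_parcels))
  parcel_id <- .voronoi_labels(nr, nc, farm_cells, seeds)

  # per-parcel primary use: greedy fill of a random parcel order until the
  # crop share of farmland cells reaches its target (granularity of one
  # parcel, well inside the +-2pp proportion tolerance at desk scale)
  farm_share <- p[["crop"]] + p[["pasture"]] + p[["other"]]
  crop_target <- p[["crop"]] / (p[["crop"]] + p[["pasture"]])
  other_target <- p[["other"]] / farm_share
  parcel_sizes <- tabulate(parcel_id[farm_cells], nbins = config$n_parcels)
  perm <- sample.int(config$n_parcels)
  cum_before <- cumsum(c(0, parcel_sizes[perm]))[seq_along(perm)] /
    length(farm_cells)
  is_crop <- logical(config$n_parcels)
  is_crop[perm[cum_before < crop_target]] <- TRUE
  landuse[farm_cells] <- ifelse(is_crop[parcel_id[farm_cells]],
                                codes[["CROP"]], codes[["PASTURE"]])

  # sprinkle OTHER cells inside parcels, protecting each parcel's seed cell
  sprinkle <- farm_cells[stats::runif(length(farm_cells)) < other_target]
  sprinkle <- setdiff(sprinkle, seeds)
  landuse[sprinkle] <- codes[["OTHER"]]

  slope <- 15 * stats::pnorm(f_slope)   # percent
  dist_water <- distance_transform(landuse == codes[["WATER"]],
                                   config$cell_size)
  dist_forest <- distance_transform(landuse == codes[["FOREST"]],
                                    config$cell_size)
  srr <- (0.6 + 0.9 * stats::pnorm(f_prod)) * config$cash_rent

  ebi <- .ebi_layers(nr, nc, sm, config$ebi_shared)

  structure(list(
    landuse = landuse, parcel_id = parcel_id, slope = slope,
    dist_water = dist_water, dist_forest = dist_forest, srr = srr,
    ebi = ebi, cell_size = config$cell_size, config = config, seed = seed
  ), class = "crp_landscape")
}

#' @export
print.crp_landscape <- function(x, ...) {
  codes <- landuse_codes()
  shares <- table(factor(x$landuse, levels = codes,
                         labels = names(codes))) / length(x$landuse)
  cat("Synthetic landscape:", nrow(x$landuse), "x", ncol(x$landuse),
      "cells at", x$cell_size, "m;",
      max(x$parcel_id), "parcels\n")
  cat("  land-use shares:",
      paste(names(shares), sprintf("%.1f%%", 100 * shares),
            collapse = ", "), "\n")
  invisible(x)
}

# Gaussian-smoothed standard-normal random field via circular (FFT)
# convolution; returned field has mean 0, sd 1 over cells.
.smooth_field <- function(nr, nc, sigma) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma > 0) {
    kr <- stats::dnorm(.wrapped_offsets(nr), sd = sigma)
    kc <- stats::dnorm(.wrapped_offsets(nc), sd = sigma)
    kern <- outer(kr, kc)
    kern <- kern / sum(kern)
    z <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) /
      (nr * nc)
  }
  (z - mean(z)) / stats::sd(z)
}

.wrapped_offsets <- function(n) {
  i <- seq_len(n) - 1L
  pmin(i, n - i)
}

# Nearest-seed labels over the given cells (1-based linear indices); cells
# not in `cells` get label 0.
.voronoi_labels <- function(nr, nc, cells, seeds) {
  rows <- (cells - 1L) %% nr + 1L
  cols <- (cells - 1L) %/% nr + 1L
  srows <- (seeds - 1L) %% nr + 1L
  scols <- (seeds - 1L) %/% nr + 1L
  best <- rep(Inf, length(cells))
  lab <- integer(length(cells))
  for (s in seq_along(seeds)) {
    d2 <- (rows - srows[s])^2 + (cols - scols[s])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    lab[upd] <- s
  }
  out <- matrix(0L, nr, nc)
  out[cells] <- lab
  out
}

# Six composite EBI surfaces: z-scored variant layers sharing a latent
# field (variance fraction w), combined with point-scale weights
# 150 (N1, 3 variants) + 100 (N2, 2 variants) + 50 (N3), then min-max
# rescaled into [50, 350] per layer.
.ebi_layers <- function(nr, nc, sm, w) {
  L <- .smooth_field(nr, nc, sm)
  mix <- function() sqrt(w) * L + sqrt(1 - w) * .smooth_field(nr, nc, sm)
  n1 <- list(mix(), mix(), mix())
  n2 <- list(mix(), mix())
  n3 <- mix()
  out <- vector("list", 6L)
  idx <- 0L
  for (a in 1:3) {
    for (b in 1:2) {
      idx <- idx + 1L
      z <- 150 * n1[[a]] + 100 * n2[[b]] + 50 * n3
      out[[idx]] <- 50 + 300 * (z - min(z)) / (max(z) - min(z))
    }
  }
  names(out) <- paste0("ebi", 1:6)
  out
}

#' Exact Euclidean distance transform
#'
#' Distance from every cell to the nearest `TRUE` cell of a mask, measured
#' centre-to-centre and scaled by the cell size (Felzenszwalb &
#' Huttenlocher two-pass algorithm; exact, not an approximation).
#'
#' @param mask Logical matrix with at least one `TRUE` cell.
#' @param cell_size Cell edge length in metres (default 1 returns cell
#'   units).
#' @return Numeric matrix of distances in metres.
#' @examples
#' m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE
#' distance_transform(m, 30)
#' @export
distance_transform <- function(mask, cell_size = 1) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("mask has no TRUE cell", call. = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  # sentinel for columns without a mask cell: larger than any true distance
  # but small enough that parabola arithmetic stays exact in doubles
  big <- nr + nc + 1
  # pass 1: per column, distance (in rows) to the nearest TRUE in-column
  g <- matrix(big, nr, nc)
  for (j in seq_len(nc)) {
    col <- mask[, j]
    if (!any(col)) next
    d <- rep(big, nr)
    run <- big
    for (i in seq_len(nr)) {
      run <- if (col[i]) 0 else min(run + 1, big)
      d[i] <- run
    }
    run <- big
    for (i in rev(seq_len(nr))) {
      run <- if (col[i]) 0 else min(run + 1, big)
      d[i] <- min(d[i], run)
    }
    g[, j] <- d
  }
  # pass 2: per row, lower envelope of parabolas over squared distances
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    out[i, ] <- .dt1d(g[i, ]^2)
  }
  sqrt(out) * cell_size
}

# 1-D squared-distance transform of a sampled function (Felzenszwalb &
# Huttenlocher 2012, Theory of Computing 8).
.dt1d <- function(f) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  if (n > 1L) {
    for (q in 2:n) {
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
      while (s <= z[k]) {
        k <- k - 1L
        s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
      }
      k <- k + 1L
      v[k] <- q
      z[k] <- s
      z[k + 1L] <- Inf
    }
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Eligibility mask for enrollment
#'
#' Cells eligible for conservation enrollment: cropland and pasture.
#' Already-converted fallow land, forest, water and other uses are not
#' eligible.
#'
#' @param landuse Integer matrix of land-use codes (see [landuse_codes()]).
#' @return Logical matrix.
#' @export
eligibility_mask <- function(landuse) {
  codes <- landuse_codes()
  if (!all(landuse %in% codes)) {
    stop("unknown land-use code in raster", call. = FALSE)
  }
  matrix(landuse %in% codes[c("CROP", "PASTURE")], nrow(landuse),
         ncol(landuse))
}

#' Read and write ESRI ASCII grids
#'
#' Lossless round-trip of a numeric raster in the ESRI ASCII grid exchange
#' format (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value` header; values row-major from the top row).  Floating
#' layers are written with full precision.
#'
#' @param path File path.
#' @param raster Numeric matrix; `NA` cells are written as the NODATA value.
#' @param cell_size Cell size recorded in the header.
#' @param xll,yll Lower-left corner coordinates.
#' @param nodata NODATA sentinel.
#' @return `read_grid` returns a numeric matrix with attributes
#'   `cell_size`, `xll`, `yll`; `write_grid` returns `path` invisibly.
#' @export
write_grid <- function(raster, path, cell_size = 30, xll = 0, yll = 0,
                       nodata = -9999) {
  stopifnot(is.matrix(raster))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(raster)),
    paste("nrows", nrow(raster)),
    paste("xllcorner", format(xll, digits = 15)),
    paste("yllcorner", format(yll, digits = 15)),
    paste("cellsize", format(cell_size, digits = 15)),
    paste("NODATA_value", format(nodata, digits = 15))
  ), con)
  vals <- raster
  vals[is.na(vals)] <- nodata
  for (i in seq_len(nrow(vals))) {
    writeLines(paste(format(vals[i, ], digits = 9, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
           "nodata_value")
  if (!all(req %in% names(hdr))) {
    stop("malformed ESRI ASCII grid header in ", path, call. = FALSE)
  }
  body <- lines[-(1:6)]
  vals <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("grid body does not match header dimensions in ", path,
         call. = FALSE)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  attr(m, "cell_size") <- hdr$cellsize
  attr(m, "xll") <- hdr$xllcorner
  attr(m, "yll") <- hdr$yllcorner
  m
}

#' Write or read a landscape bundle
#'
#' Persists every raster of a landscape as an ESRI ASCII grid in a
#' directory, together with a JSON manifest naming the layers.
#'
#' @param landscape A `crp_landscape`.
#' @param dir Directory path (created if missing).
#' @return `write_landscape` returns `dir` invisibly; `read_landscape`
#'   returns the `crp_landscape`.
#' @export
write_landscape <- function(landscape, dir) {
  stopifnot(inherits(landscape, "crp_landscape"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cs <- landscape$cell_size
  layers <- c("landuse", "parcel_id", "slope", "dist_water", "dist_forest",
              "srr")
  for (nm in layers) {
    write_grid(landscape[[nm]], file.path(dir, paste0(nm, ".asc")),
               cell_size = cs)
  }
  for (nm in names(landscape$ebi)) {
    write_grid(landscape$ebi[[nm]], file.path(dir, paste0(nm, ".asc")),
               cell_size = cs)
  }
  manifest <- list(cell_size = cs, layers = as.list(layers),
                   ebi_layers = as.list(names(landscape$ebi)),
                   seed = landscape$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  rd <- function(nm) {
    m <- read_grid(file.path(dir, paste0(nm, ".asc")))
    attributes(m) <- attributes(m)["dim"]
    m
  }
  ls <- lapply(manifest$layers, rd)
  names(ls) <- manifest$layers
  dims <- vapply(ls, dim, integer(2))
  if (any(dims != dims[, 1])) {
    stop("bundle rasters are not co-registered", call. = FALSE)
  }
  ebi <- lapply(manifest$ebi_layers, rd)
  names(ebi) <- manifest$ebi_layers
  ls$landuse <- matrix(as.integer(ls$landuse), nrow(ls$landuse))
  ls$parcel_id <- matrix(as.integer(ls$parcel_id), nrow(ls$parcel_id))
  structure(c(ls, list(ebi = ebi, cell_size = manifest$cell_size,
                       config = NULL, seed = manifest$seed)),
            class = "crp_landscape")
}
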