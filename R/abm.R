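#' OWA decision-rule weights
#'
#' Weight vectors for the seventeen ordered-weighted-averaging decision
#' rules, generated from the regular increasing monotone quantifier
#' `Q(r) = r^alpha` over four criteria: `w_i = Q(i/4) - Q((i-1)/4)`,
#' applied to the criteria sorted in descending order.  The rule index runs
#' 0..16 in order of descending orness, i.e. from the most risk-taking
#' (OR-like, any strong criterion suffices) to the most risk-averse
#' (AND-like, all criteria must be strong); index 8 (`alpha = 1`) is the
#' plain average.
#'
#' @param rule_index Integer in 0..16.
#' @return Numeric weight vector of length 4 (non-negative, sums to 1).
#' @examples
#' owa_weights(8)   # c(.25, .25, .25, .25)
#' @export
owa_weights <- function(rule_index) {
  alphas <- c(1 / 9, 1 / 7, 1 / 5, 1 / 4, 1 / 3, 1 / 2, 2 / 3, 4 / 5, 1,
              5 / 4, 3 / 2, 2, 3, 4, 5, 7, 9)
  if (!is.numeric(rule_index) || length(rule_index) != 1L ||
      rule_index < 0 || rule_index > 16 || rule_index != floor(rule_index)) {
    stop("`rule_index` must be an integer in 0..16", call. = FALSE)
  }
  a <- alphas[rule_index + 1L]
  i <- 1:4
  (i / 4)^a - ((i - 1) / 4)^a
}

#' Orness of an OWA weight vector
#'
#' Position of the operator on the OR (max, orness 1) to AND (min, orness 0)
#' spectrum: `orness(w) = sum((n - i) * w_i) / (n - 1)`.
#'
#' @param w Weight vector.
#' @return A number in `[0, 1]`.
#' @export
owa_orness <- function(w) {
  n <- length(w)
  sum((n - seq_len(n)) * w) / (n - 1)
}

#' OWA aggregation of decision criteria
#'
#' Sorts the criteria in descending order and returns their dot product
#' with the weights.
#'
#' @param criteria Numeric vector of criteria in `[0, 1]`.
#' @param weights OWA weight vector of the same length.
#' @return A scalar in `[0, 1]`.
#' @examples
#' owa_aggregate(c(0.2, 0.8, 0.5, 1.0), c(0, 0, 0, 1))  # min = 0.2
#' @export
owa_aggregate <- function(criteria, weights) {
  if (any(criteria < 0 | criteria > 1)) {
    stop("criteria must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(length(criteria) == length(weights))
  sum(sort(criteria, decreasing = TRUE) * weights)
}

#' Enrollment density in an agent's neighbourhood
#'
#' Ratio of enrolled neighbours to all neighbours, where neighbours are the
#' other agents whose parcel centroid lies within `radius` metres of this
#' agent's centroid (the agent itself is excluded).  Returns 0 when the
#' neighbourhood is empty.
#'
#' @param agent_index Index of the agent.
#' @param enrolled Logical vector of enrollment states over all agents.
#' @param dist Matrix of pairwise centroid distances in metres.
#' @param radius Neighbourhood radius in metres.
#' @return A ratio in `[0, 1]`.
#' @export
enrollment_density <- function(agent_index, enrolled, dist, radius) {
  stopifnot(radius >= 0)
  nbr <- dist[agent_index, ] <= radius
  nbr[agent_index] <- FALSE
  if (!any(nbr)) return(0)
  sum(enrolled[nbr]) / sum(nbr)
}

#' Willingness to enroll
#'
#' OWA aggregation of the four propensity criteria, each oriented so that
#' larger means more willing: retired status (`1 - retirement` code),
#' low production (`1 - production`), land tenure, and the neighbourhood
#' enrollment density.  An agent submits an offer when willingness reaches
#' the empirical threshold of 0.87.
#'
#' @param retirement Retirement code (0 retired, 1 working).
#' @param production Normalised production value in `[0, 1]`.
#' @param tenure Tenure ratio in `[0, 1]`.
#' @param density Neighbourhood enrollment density in `[0, 1]`.
#' @param rule_index OWA rule index (0..16).
#' @return Willingness in `[0, 1]`.
#' @export
willingness <- function(retirement, production, tenure, density,
                        rule_index) {
  w <- owa_weights(rule_index)
  owa_aggregate(c(1 - retirement, 1 - production, tenure, density), w)
}

#' Willingness threshold for submitting an offer
#' @return The constant 0.87.
#' @export
willingness_threshold <- function() 0.87

#' Rank and select enrollment sites within a parcel
#'
#' Eligible cells are ranked by the mean of three within-parcel ranks —
#' distance to water ascending, distance to forest ascending, slope
#' descending — so that erodible land close to water and forest is offered
#' first.  The first `ceiling(fraction * n_eligible)` cells are selected;
#' composite ties are broken by cell index.
#'
#' @param cells Integer vector of the parcel's eligible cell indices.
#' @param fraction Fraction of eligible cells to select, in `(0, 1]`.
#' @param dist_water,dist_forest,slope Numeric rasters (or vectors indexed
#'   by cell).
#' @return Integer vector of selected cell indices, in rank order.
#' @export
select_sites <- function(cells, fraction, dist_water, dist_forest, slope) {
  if (length(cells) == 0L) return(integer(0))
  stopifnot(fraction > 0, fraction <= 1)
  ord <- rank_parcel_sites(cells, dist_water, dist_forest, slope)
  ord[seq_len(ceiling(fraction * length(cells)))]
}

#' @rdname select_sites
#' @export
rank_parcel_sites <- function(cells, dist_water, dist_forest, slope) {
  r <- (rank(dist_water[cells], ties.method = "average") +
          rank(dist_forest[cells], ties.method = "average") +
          rank(-slope[cells], ties.method = "average")) / 3
  cells[order(r, cells)]
}

#' Build an enrollment offer
#'
#' The annual payment is the sum of soil rental rates over the selected
#' sites times the per-cell acreage; the farmer's voluntary bid discounts
#' it to the discounted annual payment `dap = payment * (1 - bid)`.  The
#' offer's benefit score is the mean of the active EBI layer over the
#' sites.
#'
#' @param agent_id Agent identifier.
#' @param sites Integer vector of selected cell indices (non-empty).
#' @param srr Soil-rental-rate raster, dollars per acre per year.
#' @param ebi Active EBI raster, points.
#' @param bid Bid fraction in `[0, 0.16]`.
#' @param cell_acres Acreage of one cell.
#' @return A one-row tibble: `agent_id`, `area_units`, `annual_payment`,
#'   `bid`, `dap`, `ebi_score`, and the `sites` as a list column.
#' @export
build_offer <- function(agent_id, sites, srr, ebi, bid, cell_acres) {
  if (length(sites) == 0L) stop("offer needs at least one site",
                                call. = FALSE)
  if (bid < 0 || bid > 0.16) stop("bid must lie in [0, 0.16]",
                                  call. = FALSE)
  payment <- sum(srr[sites]) * cell_acres
  tibble::tibble(
    agent_id = agent_id, area_units = length(sites),
    annual_payment = payment, bid = bid, dap = payment * (1 - bid),
    ebi_score = mean(ebi[sites]), sites = list(sites)
  )
}

#' Program-agency scoring constants for offer ranking
#'
#' Offers are ranked by `ebi_score + (bid / bid_max) * bid_points -
#' (dap / max(dap)) * cost_points`: higher benefit, higher voluntary bid
#' and lower cost first.  Defaults mirror the EBI point scales (a full bid
#' is worth 150 points, the costliest offer loses 125).
#'
#' @param bid_points Points awarded to a maximal bid.
#' @param cost_points Points deducted from the costliest offer.
#' @param bid_max Upper end of the bid support.
#' @return A list of scoring constants.
#' @export
fsa_scoring <- function(bid_points = 150, cost_points = 125,
                        bid_max = 0.16) {
  list(bid_points = bid_points, cost_points = cost_points,
       bid_max = bid_max)
}

#' Select offers on behalf of the program agency
#'
#' Ranks offers by descending score (see [fsa_scoring()]) and accepts the
#' top `n`; ties are broken by lower discounted payment, then agent id.
#'
#' @param offers Tibble of offers as built by [build_offer()].
#' @param n Number of offers to accept (>= 0).
#' @param scoring Scoring constants from [fsa_scoring()].
#' @return The accepted subset of `offers`, in acceptance order.
#' @export
fsa_select <- function(offers, n, scoring = fsa_scoring()) {
  stopifnot(n >= 0)
  if (nrow(offers) == 0L || n == 0) return(offers[0, ])
  dap_max <- max(offers$dap)
  cost_term <- if (dap_max > 0) offers$dap / dap_max else 0
  score <- offers$ebi_score +
    (offers$bid / scoring$bid_max) * scoring$bid_points -
    cost_term * scoring$cost_points
  ord <- order(-score, offers$dap, offers$agent_id)
  offers[ord[seq_len(min(n, nrow(offers)))], ]
}

#' Area unit conversion
#'
#' Converts raster map units (cells) to acres:
#' `units * cell_size^2 / 4046.8564`.
#'
#' @param map_units Number of cells (>= 0).
#' @param cell_size Cell edge length in metres.
#' @return Acres.
#' @examples
#' area_in_acres(1, 30)       # 0.2224 acres
#' area_in_acres(24686, 30)   # about 5490 acres
#' @export
area_in_acres <- function(map_units, cell_size = 30) {
  if (any(map_units < 0)) stop("map_units must be non-negative",
                               call. = FALSE)
  map_units * cell_size^2 / 4046.8564
}

#' Inverse of [area_in_acres()]
#' @param acres Acres (>= 0).
#' @inheritParams area_in_acres
#' @return Map units (not rounded).
#' @export
acres_to_map_units <- function(acres, cell_size = 30) {
  if (any(acres < 0)) stop("acres must be non-negative", call. = FALSE)
  acres * 4046.8564 / cell_size^2
}

#' Precompute the simulation context of a landscape
#'
#' Builds everything about a landscape the simulator reuses across runs:
#' the agent table (one farmer per parcel, with parcel centroid), the
#' pairwise centroid distances, and per-parcel eligible-site rankings with
#' cumulative payment and benefit sums along the ranking, so that a run
#' only indexes into precomputed arrays.
#'
#' @param landscape A `crp_landscape`.
#' @return An object of class `crp_context`.
#' @export
landscape_context <- function(landscape) {
  stopifnot(inherits(landscape, "crp_landscape"))
  nr <- nrow(landscape$landuse)
  cs <- landscape$cell_size
  elig <- eligibility_mask(landscape$landuse)
  pid <- landscape$parcel_id
  ids <- sort(unique(pid[pid > 0L]))
  n_agents <- length(ids)

  cells_all <- which(pid > 0L)
  rows <- (cells_all - 1L) %% nr + 1L
  cols <- (cells_all - 1L) %/% nr + 1L
  lab <- match(pid[cells_all], ids)
  cx <- as.numeric(tapply(rows, lab, mean)) * cs
  cy <- as.numeric(tapply(cols, lab, mean)) * cs
  dist <- sqrt(outer(cx, cx, "-")^2 + outer(cy, cy, "-")^2)

  elig_cells <- which(pid > 0L & elig)
  lab_e <- match(pid[elig_cells], ids)
  by_parcel <- split(elig_cells, factor(lab_e, levels = seq_len(n_agents)))
  cell_acres <- area_in_acres(1, cs)
  n_layers <- length(landscape$ebi)
  ranked <- lapply(by_parcel, function(cells) {
    if (length(cells) == 0L) return(integer(0))
    rank_parcel_sites(cells, landscape$dist_water, landscape$dist_forest,
                      landscape$slope)
  })
  n_elig <- lengths(ranked)
  max_m <- max(n_elig, 1L)
  # padded cumulative-sum matrices so per-run lookups are one vectorised
  # matrix index: row = agent, column = number of sites taken
  cum_pay <- matrix(NA_real_, n_agents, max_m)
  cum_ebi <- lapply(seq_len(n_layers), function(l)
    matrix(NA_real_, n_agents, max_m))
  for (a in seq_len(n_agents)) {
    ord <- ranked[[a]]
    m <- length(ord)
    if (m == 0L) next
    cum_pay[a, seq_len(m)] <- cumsum(landscape$srr[ord]) * cell_acres
    for (l in seq_len(n_layers)) {
      cum_ebi[[l]][a, seq_len(m)] <- cumsum(landscape$ebi[[l]][ord])
    }
  }

  # neighbour counts (self excluded) for the canonical density radii, so a
  # run only has to look its radius up
  radii_km <- seq(0.5, 1.5, by = 0.1)
  nbr_counts <- vapply(radii_km * 1000,
                       function(r) colSums(dist <= r) - 1L,
                       numeric(n_agents))
  colnames(nbr_counts) <- format(radii_km, nsmall = 1)

  structure(list(
    landscape = landscape, parcel_ids = ids, n_agents = n_agents,
    centroid_dist = dist, nbr_counts = nbr_counts, radii_km = radii_km,
    ranked_sites = ranked, cum_pay = cum_pay,
    cum_ebi = cum_ebi, n_eligible = lengths(ranked),
    cell_acres = cell_acres
  ), class = "crp_context")
}

# Per-agent attribute quantiles: the run-level factor coordinate u shifts
# every agent's quantile along a low-discrepancy stride, so the population
# follows the empirical PDF while the run-to-run map stays deterministic.
# Distinct irrational strides per factor keep the three demographic
# attribute sequences from being rank-correlated across agents.
.agent_quantiles <- function(u_factor, n_agents, stride, seed_shift) {
  ids <- seq_len(n_agents)
  (u_factor + stride * ids + seed_shift) %% 1
}

.demographic_strides <- c(
  RETIREMENT = (sqrt(5) - 1) / 2,       # golden-ratio fraction
  PRODUCTION = sqrt(2) - 1,
  TENURE = sqrt(3) - 1,
  THRESHOLD = sqrt(7) - 2
)

.seed_shift <- function(master_seed, which_factor) {
  # deterministic fractional offset per (seed, factor); plastic-number
  # stride keeps shifts equidistributed over seeds
  rho <- 0.754877666246693
  ((master_seed %% 100003) * rho * which_factor) %% 1
}

#' Run the enrollment simulation
#'
#' Executes the annual signup cycle for `years` years on a prepared
#' landscape: each year the non-enrolled farmer agents evaluate their
#' willingness against the start-of-year enrollment densities, willing
#' agents build offers over their ranked eligible sites, the program
#' agency accepts the top `n`, and accepted sites convert to fallow.
#' Enrollment is absorbing over the horizon.  The result is a pure
#' function of `(landscape, factors, master_seed)`: all agent-level
#' heterogeneity is derived by deterministic quantile shifts, never from
#' the R random-number stream.
#'
#' @param landscape A `crp_landscape` or a prepared `crp_context`.
#' @param factors A one-row tibble from [transform_design()], or a named
#'   vector/list with entries `RETIREMENT`, `PRODUCTION`, `TENURE` (as
#'   values, whose population quantile shift is then the value's
#'   mid-quantile — or supply `u_RETIREMENT` etc. directly), `DE` (km),
#'   `OWA` (rule index 0..16), `LAND` (fraction), `BID` (fraction), `EBI`
#'   (layer 1..6) and `n` (annual acceptance cap).
#' @param master_seed Integer; shifts the deterministic agent-attribute
#'   streams.
#' @param years Simulation horizon (default 10, the minimum contract
#'   length).
#' @param scoring Offer-ranking constants, see [fsa_scoring()].
#' @param threshold_spread Width of the agent-level willingness-threshold
#'   heterogeneity: thresholds are uniform on
#'   `willingness_threshold() +- threshold_spread / 2` (population mean
#'   exactly the empirical 0.87 constant).  The default 0.5 represents
#'   idiosyncratic, non-modelled enrollment drivers; 0 recovers a flat
#'   population threshold.
#' @param keep_raster Whether to materialise the final land-use raster.
#' @return An object of class `crp_result`: `area_units`, `area_acres`,
#'   a `per_year` tibble (`year`, `offers`, `accepted`, `new_units`,
#'   `cum_units`), the `final_landuse` raster (or `NULL`), and run
#'   metadata.
#' @export
run_simulation <- function(landscape, factors, master_seed = 1L,
                           years = 10L, scoring = fsa_scoring(),
                           threshold_spread = 0.5, keep_raster = TRUE) {
  ctx <- if (inherits(landscape, "crp_context")) landscape else
    landscape_context(landscape)
  f <- .normalize_factors(factors)
  n_agents <- ctx$n_agents
  space <- crp_factors()

  # per-agent demographic attributes from quantile-shifted empirical PDFs
  attr_of <- function(name, idx) {
    uq <- .agent_quantiles(f$u[[name]], n_agents,
                           .demographic_strides[[name]],
                           .seed_shift(master_seed, idx))
    i <- .factor_index(space, name)
    .inverse_cdf_spec(space$kind[i], space$support[[i]], space$prob[[i]], uq)
  }
  retirement <- attr_of("RETIREMENT", 1L)
  production <- attr_of("PRODUCTION", 2L)
  tenure <- attr_of("TENURE", 3L)
  u_th <- .agent_quantiles(0, n_agents, .demographic_strides[["THRESHOLD"]],
                           .seed_shift(master_seed, 4L))
  thresholds <- willingness_threshold() + threshold_spread * (u_th - 0.5)

  w <- owa_weights(f$value[["OWA"]])
  radius_m <- f$value[["DE"]] * 1000
  land_frac <- f$value[["LAND"]]
  bid <- f$value[["BID"]]
  layer <- as.integer(f$value[["EBI"]])
  n_cap <- f$value[["n"]]

  ridx <- which(abs(ctx$radii_km * 1000 - radius_m) < 1e-6)
  nbr_count <- if (length(ridx) == 1L) ctx$nbr_counts[, ridx] else
    colSums(ctx$centroid_dist <= radius_m) - 1L

  m_sites <- ifelse(ctx$n_eligible > 0L,
                    ceiling(land_frac * ctx$n_eligible), 0L)
  has_sites <- m_sites > 0L
  payment <- numeric(n_agents)
  ebi_score <- numeric(n_agents)
  hs <- which(has_sites)
  idx <- cbind(hs, m_sites[hs])
  payment[hs] <- ctx$cum_pay[idx]
  ebi_score[hs] <- ctx$cum_ebi[[layer]][idx] / m_sites[hs]
  dap <- payment * (1 - bid)

  state <- structure(list(
    year = 0L,
    enrolled = logical(n_agents),
    accepted_units = integer(n_agents),
    enrolled_nbr = numeric(n_agents),
    ledger = list(),
    context = ctx,
    params = list(w = w, bid = bid, n_cap = n_cap, scoring = scoring,
                  m_sites = m_sites, has_sites = has_sites, dap = dap,
                  ebi_score = ebi_score, radius_m = radius_m,
                  nbr_count = nbr_count, thresholds = thresholds,
                  base_crit = cbind(1 - retirement, 1 - production,
                                    tenure, 0))
  ), class = "crp_state")

  for (yr in seq_len(years)) {
    state <- step_year(state)
  }
  per_year <- state$ledger
  enrolled <- state$enrolled
  accepted_units <- state$accepted_units

  area_units <- sum(accepted_units)
  final <- NULL
  if (keep_raster) {
    final <- ctx$landscape$landuse
    fallow_cells <- unlist(lapply(which(enrolled), function(a) {
      ctx$ranked_sites[[a]][seq_len(m_sites[a])]
    }), use.names = FALSE)
    final[fallow_cells] <- landuse_codes()[["FALLOW"]]
  }

  structure(list(
    area_units = area_units,
    area_acres = area_in_acres(area_units, ctx$landscape$cell_size),
    per_year = dplyr::bind_rows(per_year),
    enrolled = enrolled,
    final_landuse = final,
    factors = f,
    master_seed = master_seed,
    years = years
  ), class = "crp_result")
}

#' @export
print.crp_result <- function(x, ...) {
  cat("Enrollment simulation:", x$years, "years,",
      sum(x$enrolled), "parcels enrolled\n")
  cat("  fallow area:", x$area_units, "map units (",
      round(x$area_acres, 1), "acres )\n")
  invisible(x)
}

#' Advance the simulation state by one signup year
#'
#' All willingness evaluations within the year use the start-of-year
#' enrollment set, so agent order cannot influence the outcome; accepted
#' agents become (permanently) enrolled and their selected sites convert.
#'
#' @param state A `crp_state` as created inside [run_simulation()].
#' @return The updated state, with the year counter advanced and a new row
#'   appended to the per-year ledger.
#' @export
step_year <- function(state) {
  stopifnot(inherits(state, "crp_state"))
  p <- state$params
  enrolled <- state$enrolled
  density <- state$enrolled_nbr / pmax(p$nbr_count, 1L)
  density[p$nbr_count == 0L] <- 0
  crit <- p$base_crit
  crit[, 4L] <- density
  will <- .owa_rowwise(crit, p$w)
  offering <- which(!enrolled & will >= p$thresholds & p$has_sites)
  n_offers <- length(offering)
  accepted_idx <- integer(0)
  if (n_offers > 0L && p$n_cap > 0) {
    dap_o <- p$dap[offering]
    dap_max <- max(dap_o)
    cost_term <- if (dap_max > 0) dap_o / dap_max else rep(0, n_offers)
    score <- p$ebi_score[offering] +
      (p$bid / p$scoring$bid_max) * p$scoring$bid_points -
      cost_term * p$scoring$cost_points
    ord <- order(-score, dap_o, offering)
    accepted_idx <- offering[ord[seq_len(min(floor(p$n_cap), n_offers))]]
    enrolled[accepted_idx] <- TRUE
    state$accepted_units[accepted_idx] <- p$m_sites[accepted_idx]
    # incremental enrolled-neighbour counts (self excluded)
    sub <- state$context$centroid_dist[, accepted_idx, drop = FALSE] <=
      p$radius_m
    sub[cbind(accepted_idx, seq_along(accepted_idx))] <- FALSE
    state$enrolled_nbr <- state$enrolled_nbr + rowSums(sub)
  }
  state$enrolled <- enrolled
  state$year <- state$year + 1L
  state$ledger <- c(state$ledger, list(tibble::tibble(
    year = state$year, offers = n_offers, accepted = length(accepted_idx),
    new_units = sum(p$m_sites[accepted_idx]),
    cum_units = sum(state$accepted_units)
  )))
  state
}

# Row-wise OWA over a 4-column criteria matrix using a vectorised
# 4-element sorting network (5 comparators).
.owa_rowwise <- function(crit, w) {
  a <- crit[, 1L]; b <- crit[, 2L]; c_ <- crit[, 3L]; d <- crit[, 4L]
  lo1 <- pmin(a, b); hi1 <- pmax(a, b)
  lo2 <- pmin(c_, d); hi2 <- pmax(c_, d)
  top <- pmax(hi1, hi2)
  mid_hi <- pmin(hi1, hi2)
  bot <- pmin(lo1, lo2)
  mid_lo <- pmax(lo1, lo2)
  m1 <- pmax(mid_hi, mid_lo)
  m2 <- pmin(mid_hi, mid_lo)
  top * w[1L] + m1 * w[2L] + m2 * w[3L] + bot * w[4L]
}

# Accepts a transform_design() row, or a named list/vector of values with
# optional u_ entries for the demographic factors.
.normalize_factors <- function(factors) {
  if (is.data.frame(factors)) {
    stopifnot(nrow(factors) == 1L)
    factors <- as.list(factors)
  }
  factors <- as.list(factors)
  need <- c("RETIREMENT", "PRODUCTION", "TENURE", "DE", "OWA", "LAND",
            "BID", "EBI", "n")
  missing <- setdiff(need, names(factors))
  if (length(missing) > 0L) {
    stop("incomplete factor vector; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  values <- lapply(factors[need], as.numeric)
  space <- crp_factors()
  u <- list()
  for (nm in c("RETIREMENT", "PRODUCTION", "TENURE")) {
    ukey <- paste0("u_", nm)
    if (!is.null(factors[[ukey]])) {
      u[[nm]] <- as.numeric(factors[[ukey]])
    } else {
      sp <- fix_factor(space, nm, values[[nm]])
      u[[nm]] <- .factor_mid_quantile(sp, nm)
    }
  }
  list(value = values, u = u)
}
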