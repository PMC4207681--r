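test_that("OWA weights come from the RIM quantifier and span the risk spectrum", {
  expect_equal(owa_weights(8), rep(0.25, 4))   # alpha = 1, plain average
  for (i in 0:16) {
    w <- owa_weights(i)
    expect_equal(sum(w), 1)
    expect_true(all(w >= 0))
  }
  orness <- vapply(0:16, function(i) owa_orness(owa_weights(i)), 0)
  expect_gt(orness[1], 0.8)            # most OR-like rule
  expect_lt(orness[17], 0.2)           # most AND-like rule
  expect_true(all(diff(orness) < 0))   # strictly decreasing across rules
  expect_equal(owa_orness(rep(0.25, 4)), 0.5)
  expect_error(owa_weights(17), "0..16")
})

test_that("OWA aggregation reduces to min, max and mean at the extremes", {
  crit <- c(0.2, 0.8, 0.5, 1.0)
  expect_equal(owa_aggregate(crit, c(0, 0, 0, 1)), 0.2)
  expect_equal(owa_aggregate(crit, c(1, 0, 0, 0)), 1.0)
  expect_equal(owa_aggregate(crit, rep(0.25, 4)), 0.625)
  expect_error(owa_aggregate(c(0.5, 1.2, 0, 0), rep(0.25, 4)), "\\[0, 1\\]")
})

test_that("more OR-like rules never decrease willingness", {
  set.seed(2)
  for (rep in 1:50) {
    crit <- runif(4)
    w <- vapply(0:16, function(i)
      owa_aggregate(crit, owa_weights(i)), 0)
    expect_true(all(diff(w) <= 1e-12))
  }
})

test_that("enrollment density is the enrolled share of in-radius neighbours", {
  dist <- as.matrix(dist(cbind(seq(0, 1000, by = 100), 0)))
  enrolled <- rep(FALSE, 11); enrolled[c(2, 3, 4)] <- TRUE
  expect_equal(enrollment_density(1, enrolled, dist, 350), 3 / 3)
  expect_equal(enrollment_density(11, enrolled, dist, 350), 0)
  expect_equal(enrollment_density(1, enrolled, dist, 1e6), 3 / 10)
  expect_equal(enrollment_density(1, enrolled, dist, 10), 0)  # no neighbours
})

test_that("willingness combines the oriented criteria and has the 0.87 threshold", {
  expect_equal(willingness_threshold(), 0.87)
  for (i in c(0, 8, 16)) {
    expect_equal(willingness(0, 0, 1, 1, i), 1)
    expect_equal(willingness(1, 1, 0, 0, i), 0)
  }
  # retired counts toward willingness, high production against it
  expect_gt(willingness(0, 0.2, 0.6, 0, 8), willingness(1, 1, 0.6, 0, 8))
})

test_that("site selection ranks by the composite of the three criteria", {
  # toy parcel of 3 cells: composite rank oracle by hand
  dw <- c(10, 20, 30); df <- c(30, 20, 10); sl <- c(5, 5, 5)
  # ranks: dw (1,2,3); df (3,2,1); slope all tied (2,2,2) -> composite
  # (2,2,2): full tie, broken by cell index
  expect_equal(select_sites(1:3, 1, dw, df, sl), 1:3)
  # steeper slope wins when distances tie
  dw2 <- c(10, 10); df2 <- c(10, 10); sl2 <- c(2, 8)
  expect_equal(select_sites(1:2, 1, dw2, df2, sl2), c(2L, 1L))
  # ceiling rule: fraction 0.5 of 7 cells -> 4
  expect_length(select_sites(1:7, 0.5, runif(7), runif(7), runif(7)), 4L)
  expect_length(select_sites(1:7, 1, runif(7), runif(7), runif(7)), 7L)
  expect_equal(select_sites(integer(0), 0.5, 1, 1, 1), integer(0))
})

test_that("offers carry the discounted payment identity", {
  srr <- rep(100, 10); ebi <- rep(200, 10)
  off <- build_offer(1L, 1:4, srr, ebi, bid = 0.10, cell_acres = 0.25)
  expect_equal(off$annual_payment, 100)
  expect_equal(off$dap, 90)
  expect_equal(off$ebi_score, 200)
  off0 <- build_offer(1L, 1:4, srr, ebi, bid = 0, cell_acres = 0.25)
  expect_equal(off0$dap, off0$annual_payment)
  expect_error(build_offer(1L, 1:4, srr, ebi, bid = 0.2,
                           cell_acres = 0.25), "bid")
  expect_error(build_offer(1L, integer(0), srr, ebi, 0.1, 0.25), "site")
})

test_that("agency selection ranks by benefit, bid and cost with stable ties", {
  offers <- dplyr::bind_rows(
    build_offer(1L, 1:2, rep(100, 9), rep(200, 9), 0.05, 0.25),
    build_offer(2L, 1:2, rep(100, 9), rep(200, 9), 0.10, 0.25),
    build_offer(3L, 1:4, rep(100, 9), rep(300, 9), 0.05, 0.25)
  )
  expect_equal(nrow(fsa_select(offers, 0)), 0L)
  expect_equal(nrow(fsa_select(offers, 10)), 3L)
  top2 <- fsa_select(offers, 2)
  # the higher bid outranks; the high-EBI but costly offer comes second
  expect_equal(top2$agent_id, c(2L, 3L))
  # between two otherwise equal offers, the higher bid is accepted first
  pair <- fsa_select(offers[1:2, ], 1)
  expect_equal(pair$agent_id, 2L)
  # equal scores fall back to lower dap then agent id
  same <- dplyr::bind_rows(
    build_offer(5L, 1:2, rep(100, 9), rep(200, 9), 0.05, 0.25),
    build_offer(4L, 1:2, rep(100, 9), rep(200, 9), 0.05, 0.25)
  )
  expect_equal(fsa_select(same, 1)$agent_id, 4L)
})

test_that("area conversion matches the 30 m cell closed form", {
  expect_equal(area_in_acres(0), 0)
  expect_equal(area_in_acres(1, 30), 900 / 4046.8564)
  expect_equal(round(area_in_acres(1, 30), 4), 0.2224)
  expect_equal(round(acres_to_map_units(5490, 30) / 100) * 100, 24700)
  expect_error(area_in_acres(-1), "non-negative")
})

test_that("simulation runs are pure functions of landscape, factors and seed", {
  ctx <- small_context()
  sp <- crp_factors()
  v <- transform_design(sp, rep(0.21, 9))
  r1 <- run_simulation(ctx, v, master_seed = 5)
  r2 <- run_simulation(ctx, v, master_seed = 5)
  expect_identical(r1$area_units, r2$area_units)
  expect_identical(r1$per_year, r2$per_year)
  expect_identical(r1$final_landuse, r2$final_landuse)
})

test_that("the simulator honours the annual cap and the conservation contract", {
  ctx <- small_context()
  sp <- crp_factors()
  set.seed(31)
  codes <- landuse_codes()
  L <- ctx$landscape
  for (rep in 1:6) {
    v <- transform_design(sp, runif(9) * 0.999)
    r <- run_simulation(ctx, v, master_seed = rep)
    expect_true(all(r$per_year$accepted <= v$n))
    expect_true(all(diff(r$per_year$cum_units) >= 0))
    expect_equal(r$area_units,
                 sum(r$final_landuse == codes[["FALLOW"]]))
    # only eligible farmland converts; everything else is a fixed point
    changed <- which(r$final_landuse != L$landuse)
    expect_true(all(L$landuse[changed] %in%
                      codes[c("CROP", "PASTURE")]))
    expect_true(all(r$final_landuse[changed] == codes[["FALLOW"]]))
    expect_lte(r$area_units, sum(eligibility_mask(L$landuse)))
    expect_lte(sum(r$per_year$accepted), 10 * v$n)
  }
})

test_that("a zero acceptance cap yields zero fallow area", {
  ctx <- small_context()
  f <- list(RETIREMENT = 1, PRODUCTION = 1, TENURE = 1, DE = 1, OWA = 0,
            LAND = 0.5, BID = 0.05, EBI = 1, n = 0)
  r <- run_simulation(ctx, f, master_seed = 1)
  expect_equal(r$area_units, 0L)
  expect_equal(sum(r$per_year$accepted), 0L)
})

test_that("an incomplete factor vector is rejected", {
  expect_error(run_simulation(small_context(), list(LAND = 0.5)),
               "incomplete")
})

test_that("raising the acceptance cap never shrinks final fallow area", {
  ctx <- small_context()
  sp <- crp_factors()
  set.seed(17)
  for (rep in 1:4) {
    u <- runif(8) * 0.999
    areas <- vapply(c(18, 23, 28), function(nv) {
      v <- transform_design(fix_factor(sp, "n", nv), matrix(u, nrow = 1))
      run_simulation(ctx, v, master_seed = 9,
                     keep_raster = FALSE)$area_units
    }, 0)
    expect_true(all(diff(areas) >= 0))
  }
})
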