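test_that("experiment run counts follow the design formula", {
  ctx <- small_context()
  cfg <- experiment_config(name = "smoke", N = 4, master_seed = 2,
                           n_boot = 50)
  rep1 <- run_experiment(cfg, context = ctx)
  expect_equal(rep1$run_count, 4 * (2 * 9 + 2))   # 80
  expect_s3_class(rep1$sa, "sensitivity_result")
  expect_equal(rep1$sa$k, 9L)
  expect_equal(glance(rep1)$runs, 80L)
  expect_s3_class(tidy(rep1), "tbl_df")
  expect_s3_class(autoplot(rep1), "ggplot")
})

test_that("experiments re-run to identical reports", {
  ctx <- small_context()
  cfg <- experiment_config(name = "det", N = 4, master_seed = 11,
                           n_boot = 20)
  a <- run_experiment(cfg, context = ctx)
  b <- run_experiment(cfg, context = ctx)
  expect_identical(a$runs$output, b$runs$output)
  expect_identical(a$sa$factors, b$sa$factors)
  expect_identical(a$ua$mean, b$ua$mean)
})

test_that("exploratory simplification fixes exactly the negligible factors", {
  ctx <- small_context()
  cfg <- experiment_config(name = "base", N = 8, master_seed = 2,
                           n_boot = 50)
  rep1 <- run_experiment(cfg, context = ctx)
  ranked <- rank_factors(rep1$sa, threshold = 0.01)
  neg <- ranked$name[ranked$negligible]
  cfg2 <- simplify_exploratory(rep1, threshold = 0.01)
  fixed <- cfg2$space$name[!is.na(cfg2$space$fixed)]
  expect_setequal(fixed, neg)
  # fixed at the distribution median
  for (nm in neg) {
    expect_equal(cfg2$space$fixed[cfg2$space$name == nm],
                 factor_median(cfg$space, nm))
  }
  # threshold 0 fixes nothing
  cfg0 <- simplify_exploratory(rep1, threshold = 0)
  expect_equal(free_factors(cfg0$space), cfg$space$name)
  # threshold 1 would fix everything -> guarded
  expect_error(simplify_exploratory(rep1, threshold = 1.5), "negligible")
})

test_that("explanatory refinement fixes the top-S factor at its midpoint", {
  # construct a report whose sensitivity comes from a real design run on a
  # model driven purely by the acceptance-cap factor
  space <- crp_factors()
  design <- saltelli_design(9, 16)
  model <- function(u) {
    vals <- transform_design(space, matrix(u, nrow = 1))
    vals$n
  }
  runs <- evaluate_design(design, model)
  sa <- sobol_indices(runs, factor_names = free_factors(space), n_boot = 50)
  expect_equal(sa$factors$name[which.max(sa$factors$S)], "n")
  rep_n <- structure(list(config = experiment_config(space = space),
                          sa = sa), class = "experiment_report")
  cfg3 <- refine_explanatory(rep_n)
  expect_equal(cfg3$space$fixed[cfg3$space$name == "n"], 23)
  expect_equal(sum(!is.na(cfg3$space$fixed)), 1L)

  # a dominant continuous factor is fixed at the interval midpoint
  model_land <- function(u) {
    transform_design(space, matrix(u, nrow = 1))$LAND
  }
  runs_l <- evaluate_design(design, model_land)
  sa_l <- sobol_indices(runs_l, factor_names = free_factors(space),
                        n_boot = 50)
  rep_l <- structure(list(config = experiment_config(space = space),
                          sa = sa_l), class = "experiment_report")
  cfg_l <- refine_explanatory(rep_l)
  expect_equal(cfg_l$space$fixed[cfg_l$space$name == "LAND"], 0.5)

  # argmax ties resolve to the earlier factor in the space
  sa_tie <- sa
  sa_tie$factors$S <- rep(0.1, 9)
  rep_t <- structure(list(config = experiment_config(space = space),
                          sa = sa_tie), class = "experiment_report")
  cfg_t <- refine_explanatory(rep_t)
  expect_equal(cfg_t$space$name[!is.na(cfg_t$space$fixed)], "RETIREMENT")
})

test_that("report comparison computes the spread-reduction statistic", {
  mk <- function(mean, var, n, name) {
    structure(list(config = list(name = name),
                   ua = list(mean = mean, variance = var, n = n)),
              class = "experiment_report")
  }
  base <- mk(100, 100, 500, "b")
  cmp <- compare_reports(mk(101, 36, 500, "r"), base)
  expect_equal(cmp$spread_reduction_pct, 64)
  expect_equal(cmp$variance_ratio, 0.36)
  expect_equal(compare_reports(base, base)$spread_reduction_pct, 0)
  worse <- compare_reports(mk(99, 150, 500, "w"), base)
  expect_lt(worse$spread_reduction_pct, 0)
  expect_error(compare_reports(base, mk(1, 0, 10, "z")), "zero")
})

test_that("experiment reports serialise to CSV and JSON", {
  ctx <- small_context()
  cfg <- experiment_config(name = "io", N = 4, master_seed = 3, n_boot = 10)
  rep1 <- run_experiment(cfg, context = ctx)
  dir <- withr::local_tempdir()
  write_experiment_report(rep1, dir)
  js <- jsonlite::read_json(file.path(dir, "report.json"),
                            simplifyVector = TRUE)
  expect_equal(js$run_count, rep1$run_count)
  expect_equal(js$ua$mean, rep1$ua$mean, tolerance = 1e-12)
  runs <- utils::read.csv(file.path(dir, "runs.csv"))
  expect_equal(nrow(runs), rep1$run_count)
})
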