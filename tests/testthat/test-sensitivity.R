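test_that("diagnosis rates are diagnosed over tested with guard rails", {
  pos <- data.frame(sex = "all", age_band = "all",
                    tested = 2051, diagnosed = 115)
  r <- diagnosis_rates(pos)
  expect_equal(r$rate, 115 / 2051, tolerance = 1e-12)
  expect_equal(round(r$rate, 5), 0.05607)

  expect_equal(diagnosis_rates(data.frame(sex = "m", age_band = "y",
                                          tested = 9, diagnosed = 9))$rate, 1)
  expect_equal(diagnosis_rates(data.frame(sex = "m", age_band = "y",
                                          tested = 9, diagnosed = 0))$rate, 0)
  expect_warning(diagnosis_rates(data.frame(sex = "m", age_band = "y",
                                            tested = 0, diagnosed = 0)),
                 "zero tested")
  expect_error(diagnosis_rates(data.frame(sex = "m", age_band = "y",
                                          tested = 3, diagnosed = 5)),
               "exceeds")
})

test_that("imputation is Binomial(u, q) with exact degenerate behaviour", {
  pool <- data.frame(region_id = c("a", "b"), sex = "all", age_band = "all",
                     count = c(100, 95))
  r0 <- data.frame(sex = "all", age_band = "all", rate = 0)
  r1 <- data.frame(sex = "all", age_band = "all", rate = 1)
  expect_equal(impute_cases(pool, r0, seed = 1)$total, 0)
  imp1 <- impute_cases(pool, r1, seed = 1)
  expect_equal(imp1$total, 195)
  expect_equal(imp1$by_region$added, c(100, 95))

  # reproducibility and region aggregation
  rq <- data.frame(sex = "all", age_band = "all", rate = 115 / 2051)
  a <- impute_cases(pool, rq, seed = 7)
  b <- impute_cases(pool, rq, seed = 7)
  expect_identical(a$cells$added, b$cells$added)
  expect_equal(sum(a$by_region$added), a$total)
  expect_true(all(a$cells$added <= pool$count))
})

test_that("mean imputed count converges to sum(u_ik q_k)", {
  pool <- data.frame(region_id = "a", sex = "all", age_band = "all",
                     count = 195)
  rq <- data.frame(sex = "all", age_band = "all", rate = 115 / 2051)
  tot <- vapply(1:1000, function(s) impute_cases(pool, rq, seed = s)$total,
                numeric(1))
  expect_lt(abs(mean(tot) - 195 * 115 / 2051),
            3 * sd(tot) / sqrt(length(tot)))
})

test_that("the imputation run distribution matches the screening-programme scale", {
  pool <- data.frame(region_id = "all", sex = "all", age_band = "all",
                     count = 195)
  rq <- data.frame(sex = "all", age_band = "all", rate = 115 / 2051)
  set.seed(2024)
  tot <- vapply(1:100, function(t)
    impute_cases(pool, rq,
                 seed = substream_seed(2024, paste0("impute-", t)))$total,
    numeric(1))
  q <- quantile(tot, c(0.25, 0.5, 0.75), type = 1)
  expect_true(abs(q[2] - 11) <= 1)      # median near 11 added cases
  expect_true(abs((q[3] - q[1]) - 4) <= 1)  # IQR near 4
})

test_that("an empty undiagnosed pool reproduces the observed p-values exactly", {
  study <- small_study()
  pool <- study$pool
  pool$count <- 0L
  rates <- diagnosis_rates(study$positives)
  rep <- run_sensitivity(study$strata, study$map, pool, rates,
                         covariates = study$covariates[c("region_id",
                                                         "dist_source_km")],
                         T_runs = 5, R = 49, k_max = 4,
                         lambda_grid = c(10, 20), seed = 99)
  for (nm in names(rep$observed))
    expect_true(all(rep$runs[[nm]] == rep$observed[[nm]]))
  expect_true(all(rep$runs$added == 0))
})

test_that("imputation never alters regions without undiagnosed positives", {
  study <- small_study()
  pool <- study$pool
  pool$count[pool$region_id == study$map$region_id[1]] <- 0L
  rates <- data.frame(sex = rep(c("male", "female"), times = 5),
                      age_band = rep(c("0-4", "5-9", "10-14", "15-19", "20+"),
                                     each = 2),
                      rate = 0.9)
  imp <- impute_cases(pool, rates, seed = 3)
  r1 <- imp$by_region[imp$by_region$region_id == study$map$region_id[1], ]
  expect_equal(r1$added, 0)
})

test_that("a full sensitivity report is reproducible and well-formed", {
  study <- small_study()
  rates <- diagnosis_rates(study$positives)
  covs <- study$covariates[c("region_id", "dist_source_km", "altitude_100m")]
  r1 <- run_sensitivity(study$strata, study$map, study$pool, rates, covs,
                        T_runs = 6, R = 49, k_max = 4,
                        lambda_grid = c(10, 20), seed = 5)
  r2 <- run_sensitivity(study$strata, study$map, study$pool, rates, covs,
                        T_runs = 6, R = 49, k_max = 4,
                        lambda_grid = c(10, 20), seed = 5)
  expect_identical(r1$runs, r2$runs)
  expect_equal(nrow(r1$runs), 6)
  expect_true(all(c("scan", "meet", "regress_dist_source_km") %in%
                    names(r1$runs)))
  expect_true(all(r1$runs$added >= 0 &
                    r1$runs$added <= sum(study$pool$count)))
  expect_true(all(r1$p_summary$min <= r1$p_summary$median &
                    r1$p_summary$median <= r1$p_summary$max))
})

test_that("region-total pools can be allocated across strata", {
  totals <- data.frame(region_id = c("a", "b"), count = c(7, 5))
  comp <- data.frame(sex = c("m", "f"), age_band = "all", weight = c(1, 3))
  pool <- allocate_pool(totals, comp)
  expect_equal(sum(pool$count), 12)
  expect_equal(sum(pool$count[pool$region_id == "a"]), 7)
  # weights respected to within rounding
  a_f <- pool$count[pool$region_id == "a" & pool$sex == "f"]
  expect_true(a_f %in% c(5, 6))
})
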