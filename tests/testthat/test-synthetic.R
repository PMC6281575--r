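test_that("same seed gives identical bundles, different seeds differ", {
  a <- simulate_study(sim_config(n_regions = 15, n_examinees = 30000,
                                 expected_cases = 30), seed = 3)
  b <- simulate_study(sim_config(n_regions = 15, n_examinees = 30000,
                                 expected_cases = 30), seed = 3)
  c <- simulate_study(sim_config(n_regions = 15, n_examinees = 30000,
                                 expected_cases = 30), seed = 4)
  expect_identical(a$strata, b$strata)
  expect_identical(a$map$dist, b$map$dist)
  expect_identical(a$covariates, b$covariates)
  expect_false(identical(a$strata$cases, c$strata$cases))
})

test_that("default configuration reproduces the study scale", {
  study <- simulate_study(sim_config(), seed = 12)
  expect_equal(study$map$n_regions, 59)
  expect_equal(sum(study$strata$examinees), 295032)
  # case total: Poisson(115) -> within 3 SD
  expect_lt(abs(sum(study$strata$cases) - 115), 3 * sqrt(115))
  # screen-positives ~ Binomial(295032, 2246/295032)
  expect_lt(abs(study$ledger$n_positive - 2246), 3 * sqrt(2246))
  # undiagnosed pool ~ 195
  expect_lt(abs(sum(study$pool$count) - 195), 3 * sqrt(195))
  expect_equal(study$ledger$n_positive - study$ledger$n_confirmatory_tested,
               sum(study$pool$count))
  # 10 strata, contiguity graph connected
  expect_equal(length(unique(paste(study$strata$sex,
                                   study$strata$age_band))), 10)
  expect_true(is_connected(study$map))
})

test_that("case draws follow the configured risk surface", {
  cfg <- sim_config(n_regions = 20, bbox_km = c(60, 50), n_examinees = 40000,
                    expected_cases = 200,
                    clusters = list(list(rule = "contiguous", rr = 4,
                                         center = 5, size = 4)))
  study <- simulate_study(cfg, seed = 21)
  members <- study$truth$clusters[[1]]$members
  expect_equal(length(members), 4)
  expect_true(is_connected(study$map, members))
  expect_setequal(study$map$region_id[study$truth$r == 4], members)

  # average elevation of cases inside the cluster across redraws
  et <- expected_counts(study$strata)
  inside <- et$region_id %in% members
  ratio <- mean(vapply(1:30, function(s) {
    st <- resample_cases(study, seed = s)
    sum(st$strata$cases[st$strata$region_id %in% members])
  }, numeric(1)))
  base <- sum(study$strata$examinees[study$strata$region_id %in% members]) /
    sum(study$strata$examinees)
  expect_gt(ratio / (200 * base), 2.5)  # rr = 4 with shrinkage from mixing
})

test_that("embed_cluster rules: radius, degenerate radius, whole map", {
  study <- small_study()
  m <- study$map
  one <- embed_cluster(m, "radius", rr = 2, center = 1, radius = 0)
  expect_equal(one$members, m$region_id[1])
  expect_equal(sum(one$r == 2), 1)

  all_m <- embed_cluster(m, "contiguous", rr = 1.5, center = 1,
                         size = m$n_regions)
  expect_equal(length(all_m$members), m$n_regions)

  expect_error(embed_cluster(m, "contiguous", rr = 0, center = 1, size = 2),
               "positive")
})

test_that("a global rate shift is invisible to the conditional scan", {
  # rr uniform everywhere -> conditional-on-total null is unchanged; p ~ U
  cfg <- sim_config(n_regions = 15, bbox_km = c(40, 40), n_examinees = 30000,
                    expected_cases = 60,
                    clusters = list(list(rule = "contiguous", rr = 2,
                                         center = 1, size = 15)))
  ps <- vapply(1:20, function(s) {
    study <- simulate_study(cfg, seed = 300 + s)
    et <- expected_counts(study$strata)
    pos <- match(study$map$region_id, et$region_id)
    scan_flexible(et$observed[pos], et$expected[pos], study$map,
                  k_max = 4, R = 49, seed = s)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.25)  # no systematic significance
})

test_that("generated cases respect the conditional multinomial structure", {
  # conditional on the total, homogeneous-risk case vectors should be
  # multinomial with probabilities e/E: compare first moments
  cfg <- sim_config(n_regions = 10, bbox_km = c(30, 30), n_examinees = 20000,
                    expected_cases = 80)
  study <- simulate_study(cfg, seed = 9)
  et <- expected_counts(study$strata)
  draws <- vapply(1:200, function(s) {
    st <- resample_cases(study, seed = 5000 + s)
    o <- rowsum(st$strata$cases,
                factor(st$strata$region_id, levels = et$region_id))[, 1]
    o / sum(o)
  }, numeric(10))
  p_emp <- rowMeans(draws)
  p_exp <- et$expected / sum(et$expected)
  expect_lt(max(abs(p_emp - p_exp)), 0.03)
})

test_that("study bundles round-trip through the CSV/JSON writers", {
  study <- small_study()
  dir <- withr::local_tempdir()
  write_study(study, dir)
  m2 <- load_region_map(file.path(dir, "regions.csv"),
                        file.path(dir, "adjacency.csv"))
  st2 <- read_strata(file.path(dir, "strata.csv"))
  cov2 <- read_covariates(file.path(dir, "covariates.csv"))
  pool2 <- read_undiagnosed(file.path(dir, "undiagnosed.csv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(m2$dist, study$map$dist, tolerance = 1e-9)
  expect_equal(st2$cases, study$strata$cases)
  expect_equal(cov2, study$covariates)
  expect_equal(pool2$count, study$pool$count)
  expect_equal(truth$r, study$truth$r)
  led <- load_cohort(file.path(dir, "cohort.csv"))
  expect_equal(led$n_positive, study$ledger$n_positive)
})
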