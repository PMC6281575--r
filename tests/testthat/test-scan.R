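test_that("window statistic matches the closed form and its boundary", {
  ws <- window_statistic(5, 1, 10, 10)
  expect_equal(ws$llr, 5 * log(5) + 5 * log(5 / 9))
  expect_equal(ws$rr_inside, 5)

  ws2 <- window_statistic(42, 29.76, 115, 115)
  expect_equal(round(ws2$rr_inside, 3), 1.411)
  expect_gt(ws2$llr, 0)

  # inside ratio equal to outside ratio: indicator boundary, llr = 0
  expect_equal(window_statistic(5, 5, 10, 10)$llr, 0)
  # inside below outside: one-sided statistic stays 0
  expect_equal(window_statistic(1, 5, 10, 10)$llr, 0)
  # 0 * log(0) convention at the extremes
  expect_equal(window_statistic(0, 1, 10, 10)$llr, 0)
  expect_equal(window_statistic(10, 1, 10, 10)$llr, 10 * log(10))

  expect_error(window_statistic(5, 0, 10, 10), "e_z")
  expect_error(window_statistic(5, 10, 10, 10), "e_z")
  expect_error(window_statistic(11, 1, 10, 10), "o_z")
})

test_that("flexible enumeration on a path graph excludes disconnected pairs", {
  w <- flex_windows(path_map(), k_max = 3)
  keys <- canonical_keys(w$members)
  expect_setequal(keys, c("1", "2", "3", "1,2", "2,3", "1,2,3"))
})

test_that("flexible enumeration on a 5-star gives singletons and centre pairs", {
  w <- flex_windows(star_map(), k_max = 2)
  keys <- canonical_keys(w$members)
  # 5 singletons plus the 4 centre-leaf pairs; no leaf-leaf windows
  expect_setequal(keys, c("1", "2", "3", "4", "5",
                          "1,2", "1,3", "1,4", "1,5"))
})

test_that("flexible enumeration equals brute-force connected-subset search", {
  skip_if_not_installed("igraph")
  for (seed in c(1, 2, 3)) {
    m <- random_map(8, seed = seed, p_extra = 0.25)
    w <- flex_windows(m, k_max = 8)
    oracle <- brute_connected_subsets(m, 8)
    expect_setequal(canonical_keys(w$members), canonical_keys(oracle))
  }
})

test_that("best flexible llr equals exhaustive search and grows with k_max", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (seed in 4:6) {
    m <- random_map(7, seed = seed, p_extra = 0.3)
    e <- runif(7, 0.5, 2)
    o <- as.numeric(rmultinom(1, 30, e / sum(e)))
    e <- e * sum(o) / sum(e)
    oracle <- oracle_best_llr(brute_connected_subsets(m, 7), o, e)
    res <- scan_flexible(o, e, m, k_max = 7, R = 9, seed = 1)
    expect_equal(res$most_likely$llr, oracle, tolerance = 1e-12)

    best_by_k <- vapply(1:7, function(k)
      scan_flexible(o, e, m, k_max = k, R = 9, seed = 1)$most_likely$llr,
      numeric(1))
    expect_true(all(diff(best_by_k) >= -1e-12))
  }
})

test_that("a singleton holding all cases dominates the scan", {
  m <- random_map(6, seed = 7)
  e <- c(0.5, rep(2, 5)); o <- c(11, rep(0, 5))
  e <- e * sum(o) / sum(e)
  res <- scan_flexible(o, e, m, k_max = 3, R = 99, seed = 2)
  expect_equal(res$most_likely$regions, m$region_id[1])
  expect_lte(res$p_value, 0.05)
})

test_that("an all-zero case vector yields llr 0 and p 1", {
  m <- random_map(5, seed = 8)
  res <- scan_flexible(rep(0, 5), rep(1, 5), m, k_max = 3, R = 19, seed = 3)
  expect_equal(res$most_likely$llr, 0)
  expect_equal(res$p_value, 1)
})

test_that("circular windows are nested nearest-neighbour sets with id tie rule", {
  # four collinear regions with a distance tie broken lexicographically
  m <- region_map(data.frame(region_id = c("A", "B", "C", "D"),
                             x_km = c(0, 1, -1, 2), y_km = 0),
                  data.frame(region_a = c("A", "A", "B"),
                             region_b = c("B", "C", "D")))
  # from seed A, B and C tie at distance 1: B enters first (id order)
  ord <- arealscan:::seed_order(m, 1L)
  expect_equal(ord, c(1L, 2L, 3L, 4L))
  w <- circular_windows(m, k_max = 3)
  keys <- canonical_keys(w$members)
  expect_true("1,2" %in% keys)        # {A,B}: A's first pair
  expect_true("1,2,3" %in% keys)      # A's triple includes both tied regions
  expect_false("1,4" %in% keys)       # D is never A's nearest neighbour
})

test_that("k_max = 1 makes circular and flexible scans the per-region maximum", {
  m <- random_map(6, seed = 9)
  set.seed(4)
  e <- runif(6, 0.5, 2)
  o <- as.numeric(rmultinom(1, 25, e / sum(e)))
  e <- e * sum(o) / sum(e)
  rf <- scan_flexible(o, e, m, k_max = 1, R = 9, seed = 5)
  rc <- scan_circular(o, e, m, k_max = 1, R = 9, seed = 5)
  singles <- vapply(seq_len(6), function(i)
    window_statistic(o[i], e[i], sum(o), sum(e))$llr, numeric(1))
  expect_equal(rf$most_likely$llr, max(singles))
  expect_equal(rc$most_likely$llr, max(singles))
  expect_equal(rf$most_likely$regions, rc$most_likely$regions)
})

test_that("flexible best llr dominates circular best llr on connected circles", {
  # collinear equally spaced regions: every circular window is an interval,
  # hence connected under the path adjacency
  n <- 9
  m <- region_map(data.frame(region_id = sprintf("r%02d", 1:n),
                             x_km = 1:n, y_km = 0),
                  data.frame(region_a = sprintf("r%02d", 1:(n - 1)),
                             region_b = sprintf("r%02d", 2:n)))
  set.seed(6)
  for (rep in 1:5) {
    e <- rep(2, n)
    o <- as.numeric(rmultinom(1, 40, e / sum(e)))
    e <- e * sum(o) / sum(e)
    bf <- scan_flexible(o, e, m, k_max = 5, R = 9, seed = 7)$most_likely$llr
    bc <- scan_circular(o, e, m, k_max = 5, R = 9, seed = 7)$most_likely$llr
    expect_gte(bf + 1e-12, bc)
  }
})

test_that("interval-shaped truth is recovered by both scan shapes", {
  n <- 11
  m <- region_map(data.frame(region_id = sprintf("r%02d", 1:n),
                             x_km = 1:n, y_km = 0),
                  data.frame(region_a = sprintf("r%02d", 1:(n - 1)),
                             region_b = sprintf("r%02d", 2:n)))
  e <- rep(5, n)
  o <- rep(3, n); o[5:7] <- c(12, 14, 12)
  e <- e * sum(o) / sum(e)
  rf <- scan_flexible(o, e, m, k_max = 4, R = 99, seed = 8)
  rc <- scan_circular(o, e, m, k_max = 4, R = 99, seed = 8)
  expect_setequal(rf$most_likely$regions, sprintf("r%02d", 5:7))
  expect_setequal(rc$most_likely$regions, sprintf("r%02d", 5:7))
})

test_that("scan p-values are reproducible and windows reusable", {
  study <- small_study()
  et <- expected_counts(study$strata)
  pos <- match(study$map$region_id, et$region_id)
  o <- et$observed[pos]; e <- et$expected[pos]
  w <- flex_windows(study$map, 5)
  r1 <- scan_flexible(o, e, study$map, windows = w, R = 99, seed = 10)
  r2 <- scan_flexible(o, e, study$map, k_max = 5, R = 99, seed = 10)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$most_likely, r2$most_likely)
  expect_true(r1$p_value >= 1 / 100 && r1$p_value <= 1)
})

test_that("embedded elevated-risk clusters are recovered by the flexible scan", {
  # study-scale design: 59 regions, 115 expected cases, an RR = 3 cluster of
  # 5 contiguous regions; case tables are redrawn on a fixed geography
  cfg <- sim_config(clusters = list(list(rule = "contiguous", rr = 3,
                                         center = 20, size = 5)))
  study <- simulate_study(cfg, seed = 77)
  truth <- study$truth$clusters[[1]]$members
  w <- flex_windows(study$map, 10)
  runs <- 20
  jacs <- vapply(seq_len(runs), function(s) {
    st <- resample_cases(study, seed = 1000 + s)
    et <- expected_counts(st$strata)
    pos <- match(st$map$region_id, et$region_id)
    res <- scan_flexible(et$observed[pos], et$expected[pos], st$map,
                         windows = w, R = 19, seed = s)
    found <- res$most_likely$regions
    length(intersect(found, truth)) / length(union(found, truth))
  }, numeric(1))
  expect_gte(mean(jacs > 0.5), 0.8)
})

test_that("k_max above the region count is clamped with a warning", {
  m <- random_map(4, seed = 10)
  expect_warning(w <- flex_windows(m, k_max = 10), "clamped")
  expect_equal(w$k_max, 4L)
})
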