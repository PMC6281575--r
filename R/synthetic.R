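# Synthetic municipality-level study generator: geography, stratified
# examinees, cases under a specified risk surface, covariates, screening
# flow and the undiagnosed-positive pool.

SEXES <- c("male", "female")
AGE_BANDS <- c("0-4", "5-9", "10-14", "15-19", "20+")

#' Configuration for a synthetic areal screening study
#'
#' Defaults emulate a prefecture-scale paediatric screening programme:
#' 59 regions in a 165 x 132 km bounding box, 295,032 examinees in 10
#' sex-by-age strata, stratum prevalence rates scaled so that 115 cases are
#' expected, a screen-positive rate of 2,246/295,032 with confirmatory
#' uptake 2,051/2,246 (about 195 undiagnosed positives), and prevalence
#' rising with age and higher in females.
#'
#' @param n_regions number of regions.
#' @param bbox_km bounding box (width, height) in km.
#' @param n_examinees total examinees, allocated across regions by
#'   heavy-tailed (log-normal) weights and across strata by
#'   Dirichlet-perturbed shares.
#' @param pop_sdlog log-normal sd of the region size weights.
#' @param expected_cases target expected case total under homogeneous risk.
#' @param age_profile relative prevalence by age band (length 5).
#' @param sex_profile relative prevalence by sex (length 2, male then
#'   female).
#' @param screen_positive_rate primary-screen positivity probability.
#' @param confirmatory_uptake probability a positive undergoes confirmatory
#'   testing.
#' @param clusters list of embedded elevated-risk clusters; each element is
#'   a list with \code{rule} ("contiguous" or "radius"), \code{rr}
#'   (relative risk), \code{center} (region index or id), and \code{size}
#'   (contiguous rule) or \code{radius} in km (radius rule).
#' @param jitter coordinate jitter as a fraction of the lattice spacing.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_regions = 59, bbox_km = c(165, 132),
                       n_examinees = 295032, pop_sdlog = 1,
                       expected_cases = 115,
                       age_profile = c(0.05, 0.15, 0.6, 2.2, 3.0),
                       sex_profile = c(1, 2),
                       screen_positive_rate = 2246 / 295032,
                       confirmatory_uptake = 2051 / 2246,
                       clusters = list(), jitter = 0.15) {
  stopifnot(n_regions >= 2, length(bbox_km) == 2, all(bbox_km > 0),
            n_examinees >= 10 * n_regions,
            length(age_profile) == 5, all(age_profile > 0),
            length(sex_profile) == 2, all(sex_profile > 0),
            screen_positive_rate >= 0, screen_positive_rate <= 1,
            confirmatory_uptake >= 0, confirmatory_uptake <= 1,
            expected_cases > 0)
  for (cl in clusters)
    stopifnot(is.list(cl), cl$rr > 0, cl$rule %in% c("contiguous", "radius"))
  structure(as.list(environment()), class = "sim_config")
}

# perturbed hexagonal lattice scaled to the bounding box, with
# distance-threshold adjacency (reconnected if jitter splits the graph)
synth_geography <- function(config) {
  n <- config$n_regions
  aspect <- config$bbox_km[1] / config$bbox_km[2]
  ncol_ <- ceiling(sqrt(n * aspect))
  nrow_ <- ceiling(n / ncol_)
  row <- rep(seq_len(nrow_), each = ncol_)[seq_len(n)]
  col <- rep(seq_len(ncol_), times = nrow_)[seq_len(n)]
  x <- col + ifelse(row %% 2 == 0, 0.5, 0)
  y <- row * sqrt(3) / 2
  spacing_x <- config$bbox_km[1] / (max(x) - min(x) + 1)
  spacing_y <- config$bbox_km[2] / (max(y) - min(y) + 1)
  spacing <- min(spacing_x, spacing_y)
  x <- (x - min(x)) * spacing_x
  y <- (y - min(y)) * spacing_y
  x <- x + stats::rnorm(n, 0, config$jitter * spacing)
  y <- y + stats::rnorm(n, 0, config$jitter * spacing)
  ids <- sprintf("R%02d", seq_len(n))
  coords <- data.frame(region_id = ids, x_km = round(x, 3),
                       y_km = round(y, 3))

  d <- as.matrix(stats::dist(cbind(x, y)))
  thresh <- 1.45 * max(spacing_x, spacing_y)
  A <- d <= thresh & upper.tri(d)
  edges <- which(A, arr.ind = TRUE)
  adjacency <- data.frame(region_a = ids[edges[, 1]],
                          region_b = ids[edges[, 2]],
                          stringsAsFactors = FALSE)
  m <- region_map(coords, adjacency)
  # reconnect any components left by the jitter with their shortest bridge
  while (TRUE) {
    comp <- bfs_reachable(m$adj, 1L, seq_len(n))
    if (length(comp) == n) break
    outside <- setdiff(seq_len(n), comp)
    sub <- m$dist[comp, outside, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
    adjacency <- rbind(adjacency,
                       data.frame(region_a = ids[comp[ij[1L]]],
                                  region_b = ids[outside[ij[2L]]]))
    m <- region_map(coords, adjacency)
  }
  m
}

#' Embed an elevated-risk cluster into a risk surface
#'
#' Builds a relative-risk surface equal to \code{rr} inside a chosen
#' connected member set and 1 outside.  The \code{"contiguous"} rule grows a
#' connected set of \code{size} regions from \code{center}, repeatedly
#' adding the frontier region nearest to the centre; the \code{"radius"}
#' rule takes all regions within \code{radius} km of the centre and rejects
#' a disconnected result.
#'
#' @param map a \code{\link{region_map}}.
#' @param rule \code{"contiguous"} or \code{"radius"}.
#' @param rr relative risk inside the cluster (> 0).
#' @param center region id or index of the cluster centre.
#' @param size member count for the contiguous rule.
#' @param radius radius in km for the radius rule.
#' @return list with \code{r} (per-region risk vector) and \code{members}
#'   (region ids).
#' @export
embed_cluster <- function(map, rule = c("contiguous", "radius"), rr,
                          center, size = NULL, radius = NULL) {
  rule <- match.arg(rule)
  if (rr <= 0) abort("relative risk must be positive")
  ctr <- region_index(map, center)
  if (rule == "contiguous") {
    if (is.null(size) || size < 1 || size > map$n_regions)
      abort("contiguous rule needs a size in [1, n_regions]")
    members <- ctr
    while (length(members) < size) {
      frontier <- setdiff(unique(unlist(map$adj[members])), members)
      if (!length(frontier)) abort("cluster cannot grow further (component exhausted)")
      members <- c(members, frontier[which.min(map$dist[ctr, frontier])])
    }
  } else {
    if (is.null(radius) || radius < 0) abort("radius rule needs radius >= 0")
    members <- which(map$dist[ctr, ] <= radius)
    if (!is_connected(map, members))
      abort("regions within the requested radius are not connected")
  }
  r <- rep(1, map$n_regions)
  r[members] <- rr
  list(r = r, members = map$region_id[sort(members)])
}

# distance-decay smooth field: Gaussian kernel smoothing of iid normals
smooth_field <- function(d, range_km, z = NULL) {
  n <- nrow(d)
  if (is.null(z)) z <- stats::rnorm(n)
  K <- exp(-(d / range_km)^2)
  as.numeric(K %*% z) / rowSums(K)
}

#' Generate a complete synthetic areal screening study
#'
#' Draws geography, stratified examinee counts, cases under the configured
#' risk surface (\code{o_ik ~ Poisson(r_i pop_ik pr_k)}), regional
#' covariates (distance to a designated point source on the eastern edge
#' plus spatially smooth fields), the screening flow (positives,
#' confirmatory-tested, undiagnosed pool) and a truth record for recovery
#' scoring.  Identical seeds give identical bundles.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer master seed.
#' @return A \code{synthetic_study}: list with \code{map}, \code{strata},
#'   \code{covariates}, \code{pool} (undiagnosed per region-stratum),
#'   \code{positives} (tested/diagnosed by stratum, input to
#'   \code{\link{diagnosis_rates}}), \code{ledger}, \code{truth} (risk
#'   surface, cluster members, stratum rates) and \code{config}.
#' @export
simulate_study <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  map <- synth_geography(config)
  n <- config$n_regions

  # region sizes: 1 examinee per stratum guaranteed, remainder multinomial
  # with log-normal weights (heavy-tailed city sizes)
  w <- stats::rlnorm(n, 0, config$pop_sdlog)
  strata_grid <- expand.grid(sex = SEXES, age_band = AGE_BANDS,
                             KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = FALSE)
  K <- nrow(strata_grid)
  extra <- stats::rmultinom(1L, config$n_examinees - n * K, w)[, 1L]
  # stratum shares: Dirichlet perturbation around uniform
  pop <- matrix(0L, n, K)
  for (i in seq_len(n)) {
    g <- stats::rgamma(K, shape = 20)
    pop[i, ] <- 1L + stats::rmultinom(1L, extra[i], g / sum(g))[, 1L]
  }

  # risk surface
  r <- rep(1, n)
  truth_clusters <- list()
  for (cl in config$clusters) {
    emb <- embed_cluster(map, cl$rule, cl$rr, cl$center,
                         size = cl$size, radius = cl$radius)
    r <- r * emb$r  # overlapping clusters compound multiplicatively
    truth_clusters[[length(truth_clusters) + 1L]] <-
      list(members = emb$members, rr = cl$rr)
  }

  # stratum rates scaled so the homogeneous-risk expected total is hit
  relw <- rep(config$sex_profile, times = length(AGE_BANDS)) *
    rep(config$age_profile, each = length(SEXES))
  scale <- config$expected_cases / sum(sweep(pop, 2L, relw, `*`))
  pr_k <- relw * scale
  if (any(pr_k > 1)) abort("stratum prevalence rate above 1; rescale config")
  if (sum(sweep(pop, 2L, pr_k, `*`) * r) < 1)
    warning("expected total cases below 1 (degenerate study)")

  mu <- sweep(pop, 2L, pr_k, `*`) * r
  cases <- matrix(stats::rpois(n * K, mu), n, K)

  # screening flow
  pos <- matrix(stats::rbinom(n * K, pop, config$screen_positive_rate), n, K)
  tested <- matrix(stats::rbinom(n * K, pos, config$confirmatory_uptake),
                   n, K)
  undiag <- pos - tested

  strata <- data.frame(region_id = rep(map$region_id, each = K),
                       sex = rep(strata_grid$sex, times = n),
                       age_band = rep(strata_grid$age_band, times = n),
                       examinees = as.integer(t(pop)),
                       cases = as.integer(t(cases)),
                       stringsAsFactors = FALSE)
  pool <- data.frame(region_id = rep(map$region_id, each = K),
                     sex = rep(strata_grid$sex, times = n),
                     age_band = rep(strata_grid$age_band, times = n),
                     count = as.integer(t(undiag)),
                     stringsAsFactors = FALSE)
  # stratum-level confirmatory flow; every observed case arose from a tested
  # positive, so the tested margin is floored at the diagnosed margin
  positives <- data.frame(strata_grid,
                          tested = pmax(colSums(tested), colSums(cases)),
                          diagnosed = colSums(cases),
                          stringsAsFactors = FALSE)

  # covariates: distance to a point source on the eastern edge, smooth
  # altitude rising westwards, dose proportion decaying from the source,
  # density from the drawn populations, smooth socio-economic fields
  src <- c(config$bbox_km[1] * 0.97, config$bbox_km[2] * 0.5)
  dist_src <- sqrt((map$coords[, 1] - src[1])^2 +
                     (map$coords[, 2] - src[2])^2)
  alt <- pmax(0, (1 - map$coords[, 1] / config$bbox_km[1]) * 8 +
                2 * smooth_field(map$dist, 40))
  dose <- pmin(1, pmax(0, 0.5 * exp(-dist_src / 30) +
                         0.05 * smooth_field(map$dist, 25)))
  area_proxy <- prod(config$bbox_km) / n
  covariates <- data.frame(
    row.names = NULL,
    region_id = map$region_id,
    dist_source_km = round(dist_src, 2),
    dose_ge1msv = round(dose, 4),
    altitude_100m = round(alt, 3),
    pop_density = round(rowSums(pop) / 1000 / area_proxy, 4),
    agri_share = round(pmin(1, pmax(0, 0.12 + 0.08 * smooth_field(map$dist, 35))), 4),
    unemployment = round(pmin(1, pmax(0, 0.06 + 0.02 * smooth_field(map$dist, 30))), 4),
    professional_share = round(pmin(1, pmax(0, 0.10 + 0.04 * smooth_field(map$dist, 30))), 4),
    stringsAsFactors = FALSE)

  ledger <- cohort_filter(n_examined = sum(pop),
                          n_positive = sum(pos),
                          n_confirmatory_tested = sum(tested))
  truth <- list(r = r, clusters = truth_clusters, pr_k = pr_k,
                stratum_labels = paste(strata_grid$sex,
                                       strata_grid$age_band, sep = "|"))
  structure(list(map = map, strata = strata, covariates = covariates,
                 pool = pool, positives = positives, ledger = ledger,
                 truth = truth, config = config, seed = seed),
            class = "synthetic_study")
}

#' Redraw the case counts of a synthetic study
#'
#' Keeps the geography, populations and risk surface of an existing bundle
#' and draws a fresh Poisson case table — the cheap way to run repeated
#' calibration or power studies on a fixed design.
#'
#' @param study a \code{\link{simulate_study}} bundle.
#' @param seed integer seed for the new draw.
#' @return the study with new \code{strata$cases} (and updated
#'   \code{positives$diagnosed}/\code{tested} margins).
#' @export
resample_cases <- function(study, seed) {
  stopifnot(inherits(study, "synthetic_study"))
  set.seed(seed)
  skey <- paste(study$strata$sex, study$strata$age_band, sep = "|")
  k <- match(skey, study$truth$stratum_labels)
  i <- match(study$strata$region_id, study$map$region_id)
  mu <- study$strata$examinees * study$truth$pr_k[k] * study$truth$r[i]
  study$strata$cases <- stats::rpois(length(mu), mu)
  diag_k <- rowsum(study$strata$cases, skey)
  pk <- paste(study$positives$sex, study$positives$age_band, sep = "|")
  study$positives$diagnosed <- as.integer(diag_k[match(pk, rownames(diag_k)), 1L])
  study$positives$tested <- pmax(study$positives$tested,
                                 study$positives$diagnosed)
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study (seed %d): %d regions, %s examinees, %d cases\n",
              x$seed, x$map$n_regions,
              format(sum(x$strata$examinees), big.mark = ","),
              sum(x$strata$cases)))
  cat(sprintf("  screen-positives %d, undiagnosed pool %d, clusters: %d\n",
              x$ledger$n_positive, sum(x$pool$count),
              length(x$truth$clusters)))
  invisible(x)
}

#' Write a synthetic study bundle to a directory of CSV/JSON files
#'
#' Writes \code{regions.csv}, \code{adjacency.csv}, \code{strata.csv},
#' \code{covariates.csv}, \code{undiagnosed.csv}, \code{positives.csv},
#' \code{cohort.csv} and \code{truth.json} — the exact dialects the loader
#' functions read.
#'
#' @param study a \code{synthetic_study}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                          row.names = FALSE)
  wcsv(data.frame(region_id = study$map$region_id,
                  x_km = study$map$coords[, 1],
                  y_km = study$map$coords[, 2]), "regions.csv")
  wcsv(as.data.frame(study$map$edges), "adjacency.csv")
  wcsv(study$strata, "strata.csv")
  wcsv(study$covariates, "covariates.csv")
  wcsv(study$pool, "undiagnosed.csv")
  wcsv(study$positives, "positives.csv")
  led <- study$ledger
  led <- led[!vapply(led, is.na, logical(1L))]
  led <- led[names(led) %in% c("n_examined", "n_excluded_nonresident",
                               "n_excluded_no_municipality", "n_positive",
                               "n_confirmatory_tested")]
  wcsv(data.frame(field = names(led), value = as.numeric(led)), "cohort.csv")
  jsonlite::write_json(list(r = study$truth$r,
                            clusters = study$truth$clusters,
                            pr_k = study$truth$pr_k,
                            stratum_labels = study$truth$stratum_labels,
                            seed = study$seed),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
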