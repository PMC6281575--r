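# shared fixtures and independent oracles, built in code

make_map <- function(coords, edges) {
  region_map(coords, edges)
}

# path graph A - B - C on a line
path_map <- function() {
  region_map(data.frame(region_id = c("A", "B", "C"),
                        x_km = c(0, 1, 2), y_km = 0),
             data.frame(region_a = c("A", "B"), region_b = c("B", "C")))
}

# 5-node star: centre S with leaves L1..L4
star_map <- function() {
  region_map(data.frame(region_id = c("S", "L1", "L2", "L3", "L4"),
                        x_km = c(0, 1, -1, 0, 0), y_km = c(0, 0, 0, 1, -1)),
             data.frame(region_a = "S", region_b = c("L1", "L2", "L3", "L4")))
}

# random connected planar-ish map with n regions (seeded)
random_map <- function(n, seed, p_extra = 0.3) {
  set.seed(seed)
  xy <- matrix(runif(2 * n, 0, 10), ncol = 2)
  ids <- sprintf("r%02d", seq_len(n))
  # spanning path + random extra edges keeps it connected
  ord <- order(xy[, 1])
  edges <- cbind(ids[ord[-n]], ids[ord[-1]])
  extra <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(extra)) < p_extra
  edges <- unique(rbind(edges, cbind(ids[extra[keep, 1]],
                                     ids[extra[keep, 2]])))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  region_map(data.frame(region_id = ids, x_km = xy[, 1], y_km = xy[, 2]),
             data.frame(region_a = edges[, 1], region_b = edges[, 2]))
}

# brute-force oracle: all connected subsets of a map with <= k_max members,
# via power-set enumeration and an igraph connectivity check
brute_connected_subsets <- function(map, k_max) {
  n <- map$n_regions
  g <- igraph::graph_from_edgelist(
    cbind(match(map$edges[, 1], map$region_id),
          match(map$edges[, 2], map$region_id)), directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    if (length(idx) > k_max) next
    sg <- igraph::induced_subgraph(g, idx)
    if (igraph::components(sg)$no == 1L)
      out[[length(out) + 1L]] <- idx
  }
  out
}

canonical_keys <- function(members) {
  sort(vapply(members, function(ix) paste(sort(ix), collapse = ","),
              character(1)))
}

# independent maximiser of the Poisson window LLR over a set of windows
oracle_best_llr <- function(members, o, e) {
  O <- sum(o); E <- sum(e)
  llr <- vapply(members, function(ix) {
    oz <- sum(o[ix]); ez <- sum(e[ix])
    if (ez <= 0 || ez >= E) return(0)
    inside <- oz / ez; outside <- (O - oz) / (E - ez)
    if (inside <= outside) return(0)
    t1 <- if (oz > 0) oz * log(oz / ez) else 0
    t2 <- if (O - oz > 0) (O - oz) * log((O - oz) / (E - ez)) else 0
    t1 + t2
  }, numeric(1))
  max(llr)
}

# brute-force double-loop C-index oracle
oracle_c_index <- function(o, e, d, lambda) {
  O <- sum(o)
  acc <- 0
  for (i in seq_along(o))
    for (j in seq_along(o))
      acc <- acc + exp(-4 * (d[i, j] / lambda)^2) *
        (o[i] / O - e[i] / O) * (o[j] / O - e[j] / O)
  acc
}

# small stratified fixture: n regions x (2 sex x 2 age) strata
random_strata <- function(n, seed, rate = 5e-3) {
  set.seed(seed)
  grid <- expand.grid(sex = c("m", "f"), age_band = c("young", "old"),
                      stringsAsFactors = FALSE)
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    ex <- rpois(nrow(grid), 2000) + 50
    data.frame(region_id = sprintf("r%02d", i), sex = grid$sex,
               age_band = grid$age_band, examinees = ex,
               cases = rbinom(nrow(grid), ex, rate),
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

# tiny study bundle for fast end-to-end tests
small_study <- function(seed = 42, clusters = list()) {
  simulate_study(sim_config(n_regions = 12, bbox_km = c(40, 30),
                            n_examinees = 24000, expected_cases = 40,
                            clusters = clusters), seed = seed)
}
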