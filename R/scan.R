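# Spatial scan statistics: Poisson likelihood-ratio window statistic and
# Monte Carlo inference over flexible or circular window sets.

# vectorised one-sided Poisson log likelihood ratio; oz may be a vector or a
# matrix (windows x replicates), ez a conforming vector, O and E scalars
poisson_window_llr <- function(oz, ez, O, E) {
  outo <- O - oz
  oute <- E - ez
  # pmax keeps the 0*log(0) := 0 convention without NaN cleanup: the factor
  # in front is 0 exactly when the argument is clamped
  expand <- function(v) if (is.matrix(oz)) matrix(v, nrow(oz), ncol(oz)) else v
  t1 <- oz * log(pmax(oz, 1) / ez)
  frac <- oz > 0 & oz < 1
  if (any(frac)) { ezf <- expand(ez); t1[frac] <- oz[frac] * log(oz[frac] / ezf[frac]) }
  t2 <- outo * log(pmax(outo, 1) / oute)
  frac <- outo > 0 & outo < 1
  if (any(frac)) { ouf <- expand(oute); t2[frac] <- outo[frac] * log(outo[frac] / ouf[frac]) }
  (t1 + t2) * (oz * oute > outo * ez)
}

#' Poisson scan window statistic
#'
#' The one-sided (elevated-risk) Poisson log likelihood ratio comparing the
#' prevalence inside a scanning window with the prevalence outside:
#' \deqn{LLR = o_z \log(o_z/e_z) + (O-o_z)\log((O-o_z)/(E-e_z))}
#' when the inside rate exceeds the outside rate, and 0 otherwise (with
#' \code{0 log 0 := 0}).  Also reports the inside relative risk
#' \code{o_z / e_z}.
#'
#' @param o_z observed cases inside the window.
#' @param e_z expected cases inside the window; must satisfy
#'   \code{0 < e_z < E_total}.
#' @param O total observed cases in the study area.
#' @param E_total total expected cases (equal to \code{O} when the
#'   standardisation is internal).
#' @return list with elements \code{llr} and \code{rr_inside}.
#' @examples
#' window_statistic(42, 29.76, 115, 115)$rr_inside  # 1.411...
#' @export
window_statistic <- function(o_z, e_z, O, E_total = O) {
  stopifnot(length(o_z) == 1, length(e_z) == 1)
  if (o_z < 0 || o_z > O) abort("o_z must lie in [0, O]")
  if (e_z <= 0 || e_z >= E_total) abort("e_z must lie strictly in (0, E_total)")
  list(llr = as.numeric(poisson_window_llr(o_z, e_z, O, E_total)),
       rr_inside = o_z / e_z)
}

# deterministic ranking of windows: llr desc, then smaller window,
# then member-id key lexicographic
window_rank_order <- function(llr, windows) {
  order(-llr, windows$sizes, windows$keys, method = "radix")
}

scan_core <- function(observed, expected, map, windows, R, seed,
                      max_secondary = 5L) {
  n <- map$n_regions
  o <- as.numeric(observed); e <- as.numeric(expected)
  if (length(o) != n || length(e) != n)
    abort("observed/expected must have one entry per region")
  check_count_vector(o, "observed")
  if (any(e <= 0)) abort("expected counts must be positive in every region")
  O <- sum(o); E <- sum(e)
  if (O > 0 && abs(E - O) > 1e-6 * O)
    abort("sum(expected) must equal sum(observed) (internal standardisation)")
  if (R < 1) abort("R must be at least 1")

  W <- windows$W
  oz <- as.numeric(W %*% o)
  ez <- as.numeric(W %*% e)
  llr <- poisson_window_llr(oz, ez, O, E)
  ord <- window_rank_order(llr, windows)
  best <- ord[1L]

  # null replicates: O cases allocated multinomially with probabilities e/E
  if (!is.null(seed)) set.seed(seed)
  rep_max <- numeric(R)
  chunk <- 64L
  done <- 0L
  while (done < R) {
    k <- min(chunk, R - done)
    reps <- stats::rmultinom(k, O, e / E)
    ozr <- as.matrix(W %*% reps)
    llrm <- poisson_window_llr(ozr, ez, O, E)
    rep_max[done + seq_len(k)] <- apply(llrm, 2L, max)
    done <- done + k
  }
  p_of <- function(l) (1 + sum(rep_max >= l)) / (R + 1)

  mk <- function(w) {
    ids <- map$region_id[windows$members[[w]]]
    list(regions = ids, n_regions = length(ids),
         observed = oz[w], expected = ez[w],
         rr_inside = oz[w] / ez[w], llr = llr[w], p_value = p_of(llr[w]))
  }
  most_likely <- mk(best)

  secondary <- list()
  taken <- logical(n)
  taken[windows$members[[best]]] <- TRUE
  for (w in ord[-1L]) {
    if (length(secondary) >= max_secondary) break
    if (llr[w] <= 0) break
    mem <- windows$members[[w]]
    if (any(taken[mem])) next
    taken[mem] <- TRUE
    secondary[[length(secondary) + 1L]] <- mk(w)
  }

  structure(list(most_likely = most_likely, secondary = secondary,
                 p_value = most_likely$p_value, n_replicates = R,
                 n_windows = length(windows$members), mode = windows$type,
                 k_max = windows$k_max, seed = seed),
            class = "scan_result")
}

#' Flexibly shaped spatial scan
#'
#' Detects the most likely elevated-prevalence cluster over all connected
#' windows of at most \code{k_max} regions (see \code{\link{flex_windows}}),
#' scoring each window with the one-sided Poisson log likelihood ratio and
#' assessing the maximum by Monte Carlo simulation under the homogeneous-risk
#' null: conditional on the case total \code{O}, replicate case vectors are
#' drawn multinomially with probabilities proportional to the expected
#' counts.  The p-value uses the \code{(1 + count) / (1 + R)} estimator.
#'
#' @param observed per-region observed case counts.
#' @param expected per-region expected counts (all positive; same total as
#'   \code{observed}).
#' @param map a \code{\link{region_map}}; region order must match.
#' @param k_max maximum window size (default 15).
#' @param R Monte Carlo replicates (default 999).
#' @param seed integer seed for the replicate draws.
#' @param windows optional pre-enumerated \code{\link{flex_windows}} set;
#'   enumerating once and reusing it is the efficient way to scan many case
#'   vectors on a fixed geography.
#' @param max_secondary maximum number of non-overlapping secondary clusters
#'   to report.
#' @return A \code{scan_result}: the most likely cluster (member regions,
#'   observed, expected, relative risk, LLR, Monte Carlo p-value), secondary
#'   non-overlapping clusters in decreasing LLR order (each tested against
#'   the same replicate maxima, which is conservative), and run metadata.
#'   Ties in LLR are broken toward the smaller window, then lexicographic
#'   member ids.
#' @export
scan_flexible <- function(observed, expected, map, k_max = 15, R = 999,
                          seed = NULL, windows = NULL, max_secondary = 5L) {
  if (is.null(windows)) windows <- flex_windows(map, k_max)
  else stopifnot(inherits(windows, "scan_windows"),
                 identical(windows$region_id, map$region_id))
  scan_core(observed, expected, map, windows, R, seed, max_secondary)
}

#' Circular spatial scan
#'
#' As \code{\link{scan_flexible}} but over distance-based circular windows
#' (each seed plus its \code{j} nearest regions, \code{j < k_max}); the
#' classical baseline scan.
#'
#' @inheritParams scan_flexible
#' @return A \code{scan_result}.
#' @export
scan_circular <- function(observed, expected, map, k_max = 15, R = 999,
                          seed = NULL, windows = NULL, max_secondary = 5L) {
  if (is.null(windows)) windows <- circular_windows(map, k_max)
  else stopifnot(inherits(windows, "scan_windows"),
                 identical(windows$region_id, map$region_id))
  scan_core(observed, expected, map, windows, R, seed, max_secondary)
}

#' @export
print.scan_result <- function(x, ...) {
  ml <- x$most_likely
  cat(sprintf("%s spatial scan (k_max = %d, %d windows, R = %d)\n",
              x$mode, x$k_max, x$n_windows, x$n_replicates))
  cat(sprintf("most likely cluster: %d regions [%s]\n", ml$n_regions,
              paste(ml$regions, collapse = ", ")))
  cat(sprintf("  observed %.0f, expected %.2f, relative risk %.3f\n",
              ml$observed, ml$expected, ml$rr_inside))
  cat(sprintf("  LLR %.4f, Monte Carlo p = %.3f\n", ml$llr, ml$p_value))
  if (length(x$secondary))
    cat(sprintf("%d non-overlapping secondary cluster(s) reported\n",
                length(x$secondary)))
  invisible(x)
}
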