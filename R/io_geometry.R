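#' Construct a region map from coordinates and an adjacency edge list
#'
#' A \code{region_map} is the geographic backbone of every analysis in the
#' package: region identifiers, projected planar coordinates (km), the
#' contiguity graph, and the inter-region Euclidean distance matrix.
#' Coordinates are expected to be already projected to a rectangular plane in
#' kilometres; the package performs no geodetic transformation.
#'
#' @param coords data.frame with columns \code{region_id}, \code{x_km},
#'   \code{y_km} (one row per region). Region ids are treated as opaque
#'   strings.
#' @param adjacency data.frame (or two-column matrix) whose rows are unordered
#'   pairs of region ids sharing a border, or a symmetric logical/numeric
#'   adjacency matrix with region ids as dimnames.
#' @return An object of class \code{region_map}: a list with elements
#'   \code{region_id}, \code{coords} (n x 2 matrix), \code{dist} (n x n
#'   symmetric km matrix), \code{adj} (list of sorted neighbour indices),
#'   \code{edges} (two-column character matrix) and \code{n_regions}.
#' @examples
#' m <- region_map(
#'   data.frame(region_id = c("A", "B"), x_km = c(0, 3), y_km = c(0, 4)),
#'   data.frame(region_a = "A", region_b = "B"))
#' m$dist["A", "B"]  # 5
#' @export
region_map <- function(coords, adjacency) {
  if (!is.data.frame(coords)) abort("coords must be a data.frame")
  need <- c("region_id", "x_km", "y_km")
  if (!all(need %in% names(coords)))
    abort("coords must have columns %s", paste(need, collapse = ", "))
  ids <- as.character(coords$region_id)
  if (anyDuplicated(ids)) abort("duplicate region_id in coordinate table")
  xy <- cbind(x = as.numeric(coords$x_km), y = as.numeric(coords$y_km))
  if (!all(is.finite(xy))) abort("coordinates must be finite")
  n <- length(ids)
  rownames(xy) <- ids

  if (is.matrix(adjacency) && nrow(adjacency) == ncol(adjacency) &&
      nrow(adjacency) == n && !is.character(adjacency)) {
    A <- adjacency != 0
    if (!isTRUE(all.equal(A, t(A)))) abort("adjacency matrix must be symmetric")
    if (any(diag(A))) abort("adjacency matrix must have an empty diagonal")
    if (!is.null(rownames(A)) && !identical(rownames(A), ids))
      A <- A[ids, ids]
    ij <- which(A & upper.tri(A), arr.ind = TRUE)
    edges <- cbind(ids[ij[, 1]], ids[ij[, 2]])
  } else {
    adjacency <- as.data.frame(adjacency)
    if (ncol(adjacency) < 2L) abort("adjacency edge list needs two columns")
    edges <- cbind(as.character(adjacency[[1]]), as.character(adjacency[[2]]))
  }

  if (nrow(edges) > 0) {
    unknown <- setdiff(c(edges), ids)
    if (length(unknown))
      abort("adjacency references unknown region_id: %s",
            paste(unknown, collapse = ", "))
    if (any(edges[, 1] == edges[, 2]))
      abort("adjacency must be irreflexive (self-loop found)")
  }
  i <- match(edges[, 1], ids)
  j <- match(edges[, 2], ids)
  key <- paste(pmin(i, j), pmax(i, j))
  if (anyDuplicated(key)) {
    # a pair listed both ways is a symmetric supply, keep one copy
    keep <- !duplicated(key)
    i <- i[keep]; j <- j[keep]
  }

  adj <- rep(list(integer(0)), n)
  for (e in seq_along(i)) {
    adj[[i[e]]] <- c(adj[[i[e]]], j[e])
    adj[[j[e]]] <- c(adj[[j[e]]], i[e])
  }
  adj <- lapply(adj, function(v) sort(unique(v)))

  d <- as.matrix(stats::dist(xy))
  dimnames(d) <- list(ids, ids)
  if (any(d[upper.tri(d)] == 0))
    warning("zero distance between distinct regions (coincident coordinates)")

  structure(list(region_id = ids, coords = xy, dist = d, adj = adj,
                 edges = cbind(region_a = ids[pmin(i, j)],
                               region_b = ids[pmax(i, j)]),
                 n_regions = n),
            class = "region_map")
}

#' Read a region map from delimited files
#'
#' @param path_coords CSV with header \code{region_id,x_km,y_km}.
#' @param path_adjacency CSV with header \code{region_a,region_b}; rows are
#'   unordered contiguity pairs.
#' @return A \code{\link{region_map}}.
#' @export
load_region_map <- function(path_coords, path_adjacency) {
  for (p in c(path_coords, path_adjacency))
    if (!file.exists(p)) abort("file not found: %s", p)
  coords <- utils::read.csv(path_coords, stringsAsFactors = FALSE)
  adjacency <- utils::read.csv(path_adjacency, stringsAsFactors = FALSE)
  region_map(coords, adjacency)
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("region_map: %d regions, %d contiguity edges\n",
              x$n_regions, nrow(x$edges)))
  cat(sprintf("  extent: %.1f x %.1f km; max inter-region distance %.1f km\n",
              diff(range(x$coords[, 1])), diff(range(x$coords[, 2])),
              max(x$dist)))
  invisible(x)
}

# breadth-first search over the contiguity graph, restricted to `subset`
# (integer indices); returns the indices reachable from `from`
bfs_reachable <- function(adj, from, subset) {
  inset <- logical(length(adj))
  inset[subset] <- TRUE
  if (!inset[from]) return(integer(0))
  seen <- logical(length(adj))
  seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    nb <- adj[[v]]
    nb <- nb[inset[nb] & !seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  which(seen)
}

#' Is a set of regions connected in the contiguity graph?
#'
#' @param map a \code{\link{region_map}}.
#' @param regions character region ids (or integer indices); default all.
#' @return TRUE if the induced subgraph is connected (a single region or the
#'   empty set count as connected).
#' @export
is_connected <- function(map, regions = NULL) {
  stopifnot(inherits(map, "region_map"))
  idx <- if (is.null(regions)) seq_len(map$n_regions)
         else region_index(map, regions)
  if (length(idx) <= 1L) return(TRUE)
  length(bfs_reachable(map$adj, idx[1L], idx)) == length(idx)
}

region_index <- function(map, regions) {
  if (is.numeric(regions)) {
    idx <- as.integer(regions)
    if (any(idx < 1L | idx > map$n_regions)) abort("region index out of range")
    return(idx)
  }
  idx <- match(as.character(regions), map$region_id)
  if (anyNA(idx))
    abort("unknown region id: %s",
          paste(regions[is.na(idx)], collapse = ", "))
  idx
}

#' Cohort accounting for a two-phase screening programme
#'
#' Applies the study-subject exclusion arithmetic and the confirmatory-testing
#' ledger of a two-phase (primary screen + confirmatory work-up) programme,
#' returning the audited person counts the downstream analyses rely on:
#' analysed examinees and the pool of screen-positives who never underwent
#' confirmatory testing.
#'
#' @param n_examined persons who underwent the primary examination.
#' @param n_excluded_nonresident excluded: not resident in the study area at
#'   baseline.
#' @param n_excluded_no_municipality excluded: no residential-municipality
#'   information.
#' @param n_positive screen-positives at the primary examination.
#' @param n_confirmatory_tested positives who underwent confirmatory testing.
#' @param n_registered optional registered target population.
#' @param n_surgery,n_surgery_confirmed optional post-surgical counts; when
#'   both given the ledger reports the percentage of operated cases confirmed
#'   as carcinoma.
#' @param flags optional per-person data.frame with logical columns
#'   \code{resident}, \code{has_municipality} and optionally \code{positive},
#'   \code{confirmatory_tested}; when supplied the totals are derived from it
#'   and the count arguments are ignored.
#' @return An object of class \code{cohort_ledger} (a named list of counts)
#'   with derived fields \code{n_analysed}, \code{n_undiagnosed_positive} and
#'   optionally \code{surgical_confirmation_pct}.
#' @examples
#' cohort_filter(299908, 1523, 3353, n_positive = 2246,
#'               n_confirmatory_tested = 2051)
#' @export
cohort_filter <- function(n_examined, n_excluded_nonresident = 0,
                          n_excluded_no_municipality = 0,
                          n_positive = NA, n_confirmatory_tested = NA,
                          n_registered = NA,
                          n_surgery = NA, n_surgery_confirmed = NA,
                          flags = NULL) {
  if (!is.null(flags)) {
    stopifnot(is.data.frame(flags),
              all(c("resident", "has_municipality") %in% names(flags)))
    n_examined <- nrow(flags)
    n_excluded_nonresident <- sum(!flags$resident)
    n_excluded_no_municipality <- sum(flags$resident & !flags$has_municipality)
    if ("positive" %in% names(flags)) {
      kept <- flags$resident & flags$has_municipality
      n_positive <- sum(flags$positive & kept)
      if ("confirmatory_tested" %in% names(flags))
        n_confirmatory_tested <-
          sum(flags$positive & flags$confirmatory_tested & kept)
    }
  }
  counts <- c(n_examined = n_examined,
              n_excluded_nonresident = n_excluded_nonresident,
              n_excluded_no_municipality = n_excluded_no_municipality,
              n_positive = n_positive,
              n_confirmatory_tested = n_confirmatory_tested,
              n_registered = n_registered,
              n_surgery = n_surgery, n_surgery_confirmed = n_surgery_confirmed)
  check_count_vector(counts, "cohort counts", allow_na = TRUE)

  n_analysed <- n_examined - n_excluded_nonresident - n_excluded_no_municipality
  if (n_analysed < 0)
    abort("exclusions exceed the examined count (inconsistent input)")
  ledger <- list(n_registered = n_registered,
                 n_examined = n_examined,
                 n_excluded_nonresident = n_excluded_nonresident,
                 n_excluded_no_municipality = n_excluded_no_municipality,
                 n_analysed = n_analysed)
  if (!is.na(n_positive)) {
    ledger$n_positive <- n_positive
    if (!is.na(n_confirmatory_tested)) {
      if (n_confirmatory_tested > n_positive)
        abort("confirmatory-tested count exceeds positives")
      ledger$n_confirmatory_tested <- n_confirmatory_tested
      ledger$n_undiagnosed_positive <- n_positive - n_confirmatory_tested
    }
  }
  if (!is.na(n_surgery) && !is.na(n_surgery_confirmed)) {
    if (n_surgery_confirmed > n_surgery)
      abort("surgically confirmed count exceeds operated count")
    ledger$n_surgery <- n_surgery
    ledger$n_surgery_confirmed <- n_surgery_confirmed
    ledger$surgical_confirmation_pct <- 100 * n_surgery_confirmed / n_surgery
  }
  structure(ledger, class = "cohort_ledger")
}

#' @export
print.cohort_ledger <- function(x, ...) {
  cat("cohort ledger\n")
  for (nm in names(x))
    if (!is.na(x[[nm]]))
      cat(sprintf("  %-28s %s\n", nm,
                  format(x[[nm]], big.mark = ",", digits = 4)))
  invisible(x)
}

#' Read cohort counts from a CSV file
#'
#' The file has columns \code{field,value} with fields named as in
#' \code{\link{cohort_filter}} arguments.
#' @param path CSV path.
#' @return A \code{cohort_ledger}.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("field", "value") %in% names(tab)))
  vals <- as.list(as.numeric(tab$value))
  names(vals) <- tab$field
  do.call(cohort_filter, vals)
}
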