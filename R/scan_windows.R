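# Window enumeration for the spatial scan statistics.
#
# Flexible windows: for each seed region, every connected subset (in the
# contiguity graph) of size <= k_max drawn from the seed plus its k_max - 1
# nearest neighbours by Euclidean distance, containing the seed.  Circular
# windows: each seed plus its j nearest regions, j = 0 .. k_max - 1.  Both
# enumerations deduplicate subsets that arise from several seeds.

# distance ordering used by both scans: the seed itself first, then
# increasing distance, ties broken by region-id lexicographic order
seed_order <- function(map, seed) {
  d <- map$dist[seed, ]
  ord <- order(d, map$region_id)
  c(seed, ord[ord != seed])
}

# enumerate all connected vertex subsets containing vertex 1 of a small
# graph, with at most k_max vertices.  `nbr` is an integer vector of
# neighbour bitmasks over the candidate vertices (bit i-1 <=> vertex i).
# Binary include/exclude branching on the lowest-numbered frontier vertex;
# the forbidden mask X makes every subset appear exactly once.
enum_connected_bits <- function(nbr, k_max) {
  m <- length(nbr)
  res <- integer(1024L); nres <- 1L
  res[1L] <- 1L                       # the seed singleton, bitmask 0b1
  cap <- 256L
  Sv <- Cv <- Xv <- integer(cap); SZv <- integer(cap)
  top <- 1L
  Sv[1L] <- 1L
  Cv[1L] <- bitwAnd(nbr[1L], bitwNot(1L))
  Xv[1L] <- 0L
  SZv[1L] <- 1L
  while (top > 0L) {
    S <- Sv[top]; C <- Cv[top]; X <- Xv[top]; sz <- SZv[top]
    top <- top - 1L
    if (C == 0L || sz >= k_max) next
    v <- bitwAnd(C, -C)               # lowest set bit
    vi <- as.integer(round(log2(v))) + 1L
    C2 <- bitwXor(C, v)
    if (top + 2L > cap) {             # grow the stack
      cap <- cap * 2L
      length(Sv) <- cap; length(Cv) <- cap
      length(Xv) <- cap; length(SZv) <- cap
    }
    # branch 1: v excluded from this subtree forever
    top <- top + 1L
    Sv[top] <- S; Cv[top] <- C2; Xv[top] <- bitwOr(X, v); SZv[top] <- sz
    # branch 2: v included; frontier gains v's unseen neighbours
    S2 <- bitwOr(S, v)
    add <- bitwAnd(nbr[vi], bitwNot(bitwOr(bitwOr(S2, X), C2)))
    top <- top + 1L
    Sv[top] <- S2; Cv[top] <- bitwOr(C2, add); Xv[top] <- X
    SZv[top] <- sz + 1L
    nres <- nres + 1L
    if (nres > length(res)) length(res) <- 2L * length(res)
    res[nres] <- S2
  }
  res[seq_len(nres)]
}

bits_to_idx <- function(mask, bitv) which(bitwAnd(mask, bitv) != 0L)

new_scan_windows <- function(members, map, type, k_max) {
  nw <- length(members)
  sizes <- lengths(members)
  W <- Matrix::sparseMatrix(i = rep.int(seq_len(nw), sizes),
                            j = unlist(members, use.names = FALSE),
                            x = 1, dims = c(nw, map$n_regions))
  keys <- vapply(members,
                 function(ix) paste(map$region_id[ix], collapse = "|"),
                 character(1L))
  structure(list(members = members, sizes = sizes, W = W, keys = keys,
                 type = type, k_max = k_max, region_id = map$region_id),
            class = "scan_windows")
}

#' @export
print.scan_windows <- function(x, ...) {
  cat(sprintf("scan_windows: %d %s windows over %d regions (k_max = %d)\n",
              length(x$members), x$type, length(x$region_id), x$k_max))
  invisible(x)
}

clamp_kmax <- function(map, k_max) {
  if (k_max < 1L) abort("k_max must be at least 1")
  if (k_max > map$n_regions) {
    warning(sprintf("k_max = %d exceeds the number of regions; clamped to %d",
                    k_max, map$n_regions))
    k_max <- map$n_regions
  }
  as.integer(k_max)
}

#' Enumerate flexibly shaped scan windows
#'
#' Builds the full window set of the flexible scan: for every seed region,
#' all connected subsets (under the supplied contiguity graph) of at most
#' \code{k_max} regions drawn from the seed plus its \code{k_max - 1} nearest
#' neighbours, each containing the seed, deduplicated across seeds.  The
#' enumeration is exponential in \code{k_max}; the candidate-set restriction
#' to nearest neighbours is what keeps it tractable.
#'
#' @param map a \code{\link{region_map}}.
#' @param k_max maximum window size (default 15; at most 25).
#' @return A \code{scan_windows} object holding the member sets and a sparse
#'   membership matrix reused across Monte Carlo replicates.
#' @export
flex_windows <- function(map, k_max = 15) {
  stopifnot(inherits(map, "region_map"))
  k_max <- clamp_kmax(map, k_max)
  if (k_max > 25L) abort("k_max above 25 is not supported (window count explodes)")
  bitv <- bitwShiftL(1L, 0:(k_max - 1L))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  members <- vector("list", 4096L); nmem <- 0L
  for (seed in seq_len(map$n_regions)) {
    cand <- seed_order(map, seed)[seq_len(min(k_max, map$n_regions))]
    m <- length(cand)
    incand <- integer(map$n_regions)
    incand[cand] <- seq_len(m)
    nbr <- vapply(cand, function(v) {
      loc <- incand[map$adj[[v]]]
      loc <- loc[loc > 0L]
      as.integer(sum(bitv[loc]))
    }, integer(1L))
    masks <- enum_connected_bits(nbr, k_max)
    for (msk in masks) {
      gl <- sort(cand[bits_to_idx(msk, bitv)])
      key <- paste(gl, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      nmem <- nmem + 1L
      if (nmem > length(members)) length(members) <- 2L * length(members)
      members[[nmem]] <- gl
    }
  }
  new_scan_windows(members[seq_len(nmem)], map, "flexible", k_max)
}

#' Enumerate circular scan windows
#'
#' Windows of the distance-based circular scan: each seed region together
#' with its \code{j} nearest regions by Euclidean distance,
#' \code{j = 0 .. k_max - 1}; distance ties are resolved by region-id
#' lexicographic order.  Duplicated sets arising from different seeds are
#' emitted once.
#'
#' @inheritParams flex_windows
#' @return A \code{scan_windows} object.
#' @export
circular_windows <- function(map, k_max = 15) {
  stopifnot(inherits(map, "region_map"))
  k_max <- clamp_kmax(map, k_max)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  members <- list()
  for (seed in seq_len(map$n_regions)) {
    ord <- seed_order(map, seed)
    for (j in seq_len(k_max)) {
      gl <- sort(ord[seq_len(j)])
      key <- paste(gl, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      members[[length(members) + 1L]] <- gl
    }
  }
  new_scan_windows(members, map, "circular", k_max)
}
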