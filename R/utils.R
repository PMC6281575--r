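# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a master seed
#'
#' All Monte Carlo components of the package draw their randomness from named
#' sub-streams of one master seed, so that toggling one method on or off never
#' perturbs another method's results.
#'
#' @param master integer master seed.
#' @param name character label of the sub-stream (e.g. "scan", "meet",
#'   "impute-3").
#' @return An integer seed in [0, 2^31 - 2], a deterministic function of
#'   (master, name).
#' @export
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name),
            length(name) == 1L)
  p <- 2^31 - 1
  # polynomial rolling hash mod 2^31 - 1, seeded by the master; every
  # intermediate stays below 2^53 so doubles carry it exactly
  h <- abs(master) %% p
  for (code in utf8ToInt(name)) h <- (h * 131 + code) %% p
  as.integer(h)
}

# stop() with sprintf formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_count_vector <- function(x, name, allow_na = FALSE) {
  if (!is.numeric(x)) abort("%s must be numeric", name)
  bad <- !is.na(x) & (x < 0 | x != floor(x))
  if (any(bad)) abort("%s must contain non-negative integers", name)
  if (!allow_na && anyNA(x)) abort("%s must not contain missing values", name)
  invisible(x)
}

# order-statistic (type 1) quartile summary used for imputed-case counts
count_quartiles <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 1, names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3], iqr = q[3] - q[1])
}
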