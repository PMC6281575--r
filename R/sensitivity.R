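# Simulation-based sensitivity analysis for screen-positives who skipped
# confirmatory testing: impute hypothetical diagnoses, re-run every analysis,
# summarise the p-value distributions.

#' Stratum-specific diagnosis rates among confirmatory-tested positives
#'
#' \code{rate = diagnosed / tested} per sex-by-age stratum, assuming the rate
#' depends on sex and age only (no regional differences) — the imputation
#' probability for undiagnosed screen-positives.
#'
#' @param positives data.frame with columns \code{sex}, \code{age_band},
#'   \code{tested} (positives who underwent confirmatory testing) and
#'   \code{diagnosed} (cases among them).
#' @return the input with a \code{rate} column appended; strata with zero
#'   tested get rate 0 with a warning.
#' @export
diagnosis_rates <- function(positives) {
  stopifnot(is.data.frame(positives),
            all(c("sex", "age_band", "tested", "diagnosed") %in%
                  names(positives)))
  check_count_vector(positives$tested, "tested")
  check_count_vector(positives$diagnosed, "diagnosed")
  if (any(positives$diagnosed > positives$tested))
    abort("diagnosed count exceeds tested count in a stratum")
  if (any(positives$tested == 0 & positives$diagnosed == 0))
    warning("stratum with zero tested positives; diagnosis rate set to 0")
  positives$rate <- ifelse(positives$tested > 0,
                           positives$diagnosed / positives$tested, 0)
  positives
}

#' Impute diagnoses among undiagnosed screen-positives
#'
#' Draws \code{added_ik ~ Binomial(u_ik, q_k)} independently for every
#' region-by-stratum cell of the undiagnosed pool, where \code{q_k} is the
#' stratum diagnosis rate, and aggregates the additional hypothetical cases
#' by region.
#'
#' @param pool data.frame with columns \code{region_id}, \code{sex},
#'   \code{age_band}, \code{count} (undiagnosed screen-positives per cell).
#' @param rates a \code{\link{diagnosis_rates}} table (needs \code{sex},
#'   \code{age_band}, \code{rate}).
#' @param seed integer seed.
#' @return list with \code{cells} (the pool with an \code{added} column),
#'   \code{by_region} (data.frame \code{region_id}, \code{added}) and
#'   \code{total}.
#' @export
impute_cases <- function(pool, rates, seed = NULL) {
  stopifnot(is.data.frame(pool),
            all(c("region_id", "sex", "age_band", "count") %in% names(pool)))
  check_count_vector(pool$count, "undiagnosed counts")
  if (!all(c("sex", "age_band", "rate") %in% names(rates)))
    abort("rates must have columns sex, age_band, rate")
  if (any(rates$rate < 0 | rates$rate > 1)) abort("rates must lie in [0, 1]")
  pos <- match(paste(pool$sex, pool$age_band),
               paste(rates$sex, rates$age_band))
  if (anyNA(pos)) abort("no diagnosis rate for a stratum in the pool")
  q <- rates$rate[pos]
  if (!is.null(seed)) set.seed(seed)
  pool$added <- stats::rbinom(nrow(pool), pool$count, q)
  rid <- factor(as.character(pool$region_id),
                levels = unique(as.character(pool$region_id)))
  agg <- rowsum(pool$added, rid)
  list(cells = pool,
       by_region = data.frame(region_id = levels(rid),
                              added = as.numeric(agg[, 1L]),
                              stringsAsFactors = FALSE),
       total = sum(pool$added))
}

#' Monte Carlo sensitivity analysis of undiagnosed screen-positives
#'
#' Repeats, \code{T_runs} times: (1) impute hypothetical diagnoses among the
#' undiagnosed pool with \code{\link{impute_cases}}; (2) add them to the
#' observed stratified cases and recompute the indirect standardisation
#' (marginal rates and expected counts) from the augmented data, so that the
#' expected total tracks the augmented case total; (3) re-run the flexible
#' scan, MEET, and each univariate Poisson regression; (4) collect the
#' p-values.  The inner Monte Carlo of each method reuses one method-level
#' seed across runs (common random numbers), so that run-to-run variation
#' reflects the imputation alone; only the imputation draws vary by run.
#'
#' @param strata observed stratified counts (see \code{\link{read_strata}}).
#' @param map a \code{\link{region_map}}.
#' @param pool undiagnosed screen-positive counts per region and stratum
#'   (see \code{\link{impute_cases}}).
#' @param rates stratum diagnosis rates (see \code{\link{diagnosis_rates}}).
#' @param covariates optional covariate table for the regression arm.
#' @param methods subset of \code{c("scan", "meet", "regression")}.
#' @param T_runs number of sensitivity runs (default 100).
#' @param R inner Monte Carlo replicates for scan and MEET (default 999).
#' @param k_max,lambda_grid scan and MEET tuning parameters.
#' @param seed master seed; all imputation and method sub-seeds derive from
#'   it via \code{\link{substream_seed}}.
#' @param alpha reference level echoed in the summary (default 0.05).
#' @return A \code{sensitivity_report}: \code{runs} (data.frame with one row
#'   per run: added-case total and each method's p-value), \code{observed}
#'   (unimputed p-values), \code{added_summary} (order-statistic quartiles of
#'   added cases), \code{p_summary} (five-number summary per method), and
#'   run metadata.
#' @export
run_sensitivity <- function(strata, map, pool, rates, covariates = NULL,
                            methods = c("scan", "meet", "regression"),
                            T_runs = 100, R = 999, k_max = 15,
                            lambda_grid = seq(5, 100, by = 5),
                            seed = 1L, alpha = 0.05) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (T_runs < 1) abort("T_runs must be at least 1")
  validate_strata(strata)
  if ("regression" %in% methods && is.null(covariates))
    abort("regression requested but no covariate table supplied")

  # strata cells addressed by (region, sex, age band); pool must map into them
  skey <- paste(strata$region_id, strata$sex, strata$age_band, sep = "|")
  pkey <- paste(pool$region_id, pool$sex, pool$age_band, sep = "|")
  cell <- match(pkey, skey)
  if (anyNA(cell))
    abort("undiagnosed pool references a region/stratum absent from strata")

  seed_scan <- substream_seed(seed, "scan")
  seed_meet <- substream_seed(seed, "meet")
  windows <- if ("scan" %in% methods) flex_windows(map, k_max)

  analyse <- function(st) {
    et <- expected_counts(st)
    pos <- match(map$region_id, et$region_id)
    if (anyNA(pos)) abort("strata table is missing regions present in map")
    o <- et$observed[pos]; e <- et$expected[pos]
    p <- c()
    if ("scan" %in% methods)
      p["scan"] <- scan_flexible(o, e, map, R = R, seed = seed_scan,
                                 windows = windows)$p_value
    if ("meet" %in% methods)
      p["meet"] <- meet(o, e, map$dist, lambda_grid, R = R,
                        seed = seed_meet)$p_adjusted
    if ("regression" %in% methods) {
      cpos <- match(map$region_id, covariates$region_id)
      if (anyNA(cpos)) abort("covariate table is missing regions")
      for (nm in setdiff(names(covariates), "region_id"))
        p[paste0("regress_", nm)] <-
          fit_poisson(o, e, covariates[[nm]][cpos])$wald_p
    }
    p
  }

  observed_p <- analyse(strata)
  runs <- vector("list", T_runs)
  for (t in seq_len(T_runs)) {
    imp <- impute_cases(pool, rates,
                        seed = substream_seed(seed, paste0("impute-", t)))
    st <- strata
    st$cases[cell] <- st$cases[cell] + imp$cells$added
    runs[[t]] <- c(run = t, added = imp$total, analyse(st))
  }
  runs <- as.data.frame(do.call(rbind, runs))

  pcols <- names(observed_p)
  p_summary <- t(vapply(pcols, function(nm) {
    stats::quantile(runs[[nm]], c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  }, numeric(5L)))
  colnames(p_summary) <- c("min", "q1", "median", "q3", "max")
  p_summary <- data.frame(method = pcols, p_summary,
                          observed = as.numeric(observed_p),
                          row.names = NULL, stringsAsFactors = FALSE)

  structure(list(runs = runs, observed = observed_p,
                 added_summary = count_quartiles(runs$added),
                 p_summary = p_summary, T_runs = T_runs, R = R,
                 alpha = alpha, seed = seed, methods = methods),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  a <- x$added_summary
  cat(sprintf("sensitivity analysis: %d runs (inner R = %d, seed %d)\n",
              x$T_runs, x$R, x$seed))
  cat(sprintf("  added cases per run: median %g, IQR %g (q1 %g, q3 %g)\n",
              a["median"], a["iqr"], a["q1"], a["q3"]))
  cat("  p-value distributions (observed | min / median / max):\n")
  for (i in seq_len(nrow(x$p_summary)))
    cat(sprintf("    %-24s %.3f | %.3f / %.3f / %.3f\n",
                x$p_summary$method[i], x$p_summary$observed[i],
                x$p_summary$min[i], x$p_summary$median[i],
                x$p_summary$max[i]))
  invisible(x)
}

#' Read an undiagnosed-positive pool table
#' @param path CSV with header \code{region_id,sex,age_band,count}.
#' @return data.frame.
#' @export
read_undiagnosed <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region_id", "sex", "age_band", "count")
  if (!all(need %in% names(tab)))
    abort("undiagnosed table must have columns %s", paste(need, collapse = ", "))
  tab
}

#' Allocate region-total undiagnosed counts across strata
#'
#' Fallback for when only per-region totals of undiagnosed screen-positives
#' are known: allocates each region's total across strata proportionally to a
#' supplied screen-positive composition (largest-remainder rounding, ties to
#' the earlier stratum).
#'
#' @param totals data.frame \code{region_id}, \code{count}.
#' @param composition data.frame \code{sex}, \code{age_band}, \code{weight}
#'   (non-negative, summing to anything positive).
#' @return a pool data.frame as used by \code{\link{impute_cases}}.
#' @export
allocate_pool <- function(totals, composition) {
  stopifnot(all(c("region_id", "count") %in% names(totals)),
            all(c("sex", "age_band", "weight") %in% names(composition)))
  w <- composition$weight
  if (any(w < 0) || sum(w) <= 0) abort("weights must be non-negative, sum > 0")
  w <- w / sum(w)
  out <- lapply(seq_len(nrow(totals)), function(i) {
    n <- totals$count[i]
    exact <- n * w
    base <- floor(exact)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    data.frame(region_id = totals$region_id[i], sex = composition$sex,
               age_band = composition$age_band, count = base,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
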