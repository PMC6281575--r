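# Univariate offset Poisson ecological regression with Wald tests, quartile
# categories, trend tests, residual deviance and AIC.

#' Quartile-encode a regional covariate
#'
#' Cut points are the empirical 25/50/75 percentiles of the region values
#' (each region weighted equally; linear interpolation on the order
#' statistics, i.e. \code{quantile} type 7).  Values tied with a cut point
#' fall in the lower category; Q1 (lowest quartile) is the reference.
#'
#' @param x numeric vector, one value per region, with at least 4 distinct
#'   values.
#' @return factor with levels Q1..Q4.
#' @export
quartile_encode <- function(x) {
  if (anyNA(x)) abort("covariate contains missing values")
  if (length(unique(x)) < 4L)
    abort("quartile encoding needs at least 4 distinct values")
  cuts <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (anyDuplicated(cuts))
    abort("ties make a quartile category empty; quartile model not identifiable")
  q <- cut(x, breaks = c(-Inf, cuts, Inf),
           labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
  if (any(table(q) == 0L))
    abort("ties make a quartile category empty; quartile model not identifiable")
  q
}

glm_poisson_offset <- function(o, e, rhs_df) {
  dat <- cbind(data.frame(.o = o, .loge = log(e)), rhs_df)
  form <- if (ncol(rhs_df)) stats::as.formula(
    paste(".o ~", paste(names(rhs_df), collapse = " + "), "+ offset(.loge)"))
  else stats::as.formula(".o ~ offset(.loge)")
  fit <- stats::glm(form, family = stats::poisson(), data = dat,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  if (!fit$converged)
    abort("Poisson IRLS did not converge in 100 iterations (deviance %.4g)",
          fit$deviance)
  fit
}

coef_table <- function(fit, conf_level = 0.95) {
  s <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = rownames(s), estimate = s[, 1L], se = s[, 2L],
             rr = exp(s[, 1L]),
             rr_lo = exp(s[, 1L] - z * s[, 2L]),
             rr_hi = exp(s[, 1L] + z * s[, 2L]),
             wald_p = 2 * stats::pnorm(-abs(s[, 1L] / s[, 2L])),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Offset Poisson regression of case counts on a regional indicator
#'
#' Fits \code{o_i ~ Poisson(r_i e_i)} with \code{log(r_i) = b0 + b1 x_i}
#' (continuous form) or with quartile-category indicators of \code{x}
#' (quartile form), using the log of the standardised expected count as the
#' offset so that \code{exp(b)} are prevalence-rate ratios.  Wald p-values
#' use the normal approximation; confidence intervals are symmetric on the
#' log scale.  For the quartile form a trend test refits the model with the
#' integer quartile score (1-4) as a single continuous covariate and reports
#' the Wald p of the score coefficient.
#'
#' @param observed,expected per-region case counts and positive expected
#'   counts.
#' @param x per-region covariate values.
#' @param form \code{"continuous"} or \code{"quartile"}.
#' @param conf_level confidence level for the rate-ratio intervals.
#' @return A \code{poisson_fit}: list with \code{coefficients} (term,
#'   estimate, se, rr, rr_lo, rr_hi, wald_p), \code{wald_p} (the covariate
#'   test: slope p for continuous, category p's for quartile),
#'   \code{trend_p} (quartile form only), \code{residual_deviance},
#'   \code{aic}, \code{null_deviance}, \code{null_aic}, \code{n_regions},
#'   \code{form} and the underlying \code{glm} object.
#' @export
fit_poisson <- function(observed, expected, x = NULL,
                        form = c("continuous", "quartile"),
                        conf_level = 0.95) {
  form <- match.arg(form)
  o <- as.numeric(observed); e <- as.numeric(expected)
  check_count_vector(o, "observed")
  if (any(e <= 0)) abort("expected counts must be positive")
  n <- length(o)
  if (length(e) != n) abort("observed and expected lengths differ")

  if (is.null(x)) {
    rhs <- data.frame(row.names = seq_len(n))
    form <- "null"
  } else {
    if (length(x) != n) abort("covariate length differs from region count")
    rhs <- switch(form,
                  continuous = data.frame(x = as.numeric(x)),
                  quartile = data.frame(quartile = quartile_encode(x)))
  }
  if (!is.null(x) && form == "continuous" && stats::sd(rhs$x) == 0) {
    warning("constant covariate carries no information; fitting the null model")
    rhs <- data.frame(row.names = seq_len(n))
    form <- "null"
  }
  n_par <- if (ncol(rhs)) ncol(stats::model.matrix(~ ., rhs)) else 1L
  if (n < n_par) abort("more parameters than regions")

  fit <- glm_poisson_offset(o, e, rhs)
  null_fit <- glm_poisson_offset(o, e, data.frame(row.names = seq_len(n)))
  ct <- coef_table(fit, conf_level)

  out <- list(form = form, coefficients = ct,
              residual_deviance = fit$deviance,
              aic = fit$aic,
              null_deviance = null_fit$deviance,
              null_aic = null_fit$aic,
              loglik = as.numeric(stats::logLik(fit)),
              n_regions = n, glm = fit)
  if (form == "continuous") out$wald_p <- ct$wald_p[ct$term == "x"]
  if (form == "quartile") {
    out$wald_p <- ct$wald_p[grepl("^quartile", ct$term)]
    score <- as.integer(rhs$quartile)
    tfit <- glm_poisson_offset(o, e, data.frame(score = score))
    out$trend_p <- coef_table(tfit)$wald_p[2L]
  }
  class(out) <- "poisson_fit"
  out
}

#' Trend test across quartile categories
#'
#' Refits the offset Poisson model with the integer quartile scores (1-4) of
#' \code{x} as a single continuous covariate; the reported p is the Wald p
#' of the score coefficient (the usual epidemiological "p for trend").
#'
#' @inheritParams fit_poisson
#' @return the trend p-value (scalar).
#' @export
trend_test <- function(observed, expected, x) {
  fit_poisson(observed, expected, x, form = "quartile")$trend_p
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat(sprintf("offset Poisson regression (%s form), n = %d regions\n",
              x$form, x$n_regions))
  ct <- x$coefficients
  for (i in seq_len(nrow(ct)))
    cat(sprintf("  %-14s RR %8.3g  (%.3g, %.3g)  Wald p = %.3f\n",
                ct$term[i], ct$rr[i], ct$rr_lo[i], ct$rr_hi[i], ct$wald_p[i]))
  if (!is.null(x$trend_p)) cat(sprintf("  trend p = %.3f\n", x$trend_p))
  cat(sprintf("  residual deviance %.3f, AIC %.2f (null: %.3f, %.2f)\n",
              x$residual_deviance, x$aic, x$null_deviance, x$null_aic))
  invisible(x)
}

#' Univariate regression table over a set of regional indicators
#'
#' Fits one offset Poisson model per covariate column (continuous or
#' quartile form) and returns a table mirroring the usual ecological-study
#' reporting: rate ratio with confidence interval, Wald p, trend p (quartile
#' form), residual deviance and AIC, plus a null-model row.
#'
#' @param expected_table an \code{\link{expected_counts}} result (or any
#'   data.frame with \code{region_id}, \code{observed}, \code{expected}).
#' @param covariates data.frame with \code{region_id} plus one numeric
#'   column per indicator.
#' @param form \code{"continuous"} or \code{"quartile"}.
#' @return data.frame, one row per coefficient.
#' @export
regression_table <- function(expected_table, covariates,
                             form = c("continuous", "quartile")) {
  form <- match.arg(form)
  stopifnot(is.data.frame(covariates), "region_id" %in% names(covariates))
  pos <- match(expected_table$region_id, covariates$region_id)
  if (anyNA(pos)) abort("covariate table is missing regions")
  covs <- covariates[pos, setdiff(names(covariates), "region_id"),
                     drop = FALSE]
  o <- expected_table$observed; e <- expected_table$expected

  null_fit <- fit_poisson(o, e)
  rows <- list(data.frame(variable = "(null)", term = NA, rr = NA,
                          rr_lo = NA, rr_hi = NA, wald_p = NA, trend_p = NA,
                          residual_deviance = null_fit$residual_deviance,
                          aic = null_fit$aic, stringsAsFactors = FALSE))
  for (nm in names(covs)) {
    f <- fit_poisson(o, e, covs[[nm]], form = form)
    ct <- f$coefficients
    keep <- ct$term != "(Intercept)"
    rows[[length(rows) + 1L]] <-
      data.frame(variable = nm, term = ct$term[keep], rr = ct$rr[keep],
                 rr_lo = ct$rr_lo[keep], rr_hi = ct$rr_hi[keep],
                 wald_p = ct$wald_p[keep],
                 trend_p = if (is.null(f$trend_p)) NA else f$trend_p,
                 residual_deviance = f$residual_deviance, aic = f$aic,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Read a covariate table
#' @param path CSV with \code{region_id} plus one column per indicator.
#' @return data.frame.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"region_id" %in% names(tab)) abort("covariates need a region_id column")
  tab
}
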