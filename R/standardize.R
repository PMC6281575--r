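#' Prefecture-wide marginal prevalence rates by stratum
#'
#' Computes the marginal prevalence rate of each sex-by-age stratum across all
#' regions: \code{pr_k = (total cases in stratum k) / (total examinees in
#' stratum k)}. These are the reference rates of the indirect
#' standardisation.
#'
#' @param strata long-format data.frame with columns \code{region_id},
#'   \code{sex}, \code{age_band}, \code{examinees}, \code{cases} (one row per
#'   region x stratum; missing strata count as zero).
#' @return data.frame with one row per stratum: \code{sex}, \code{age_band},
#'   \code{examinees}, \code{cases}, \code{rate}.
#' @export
marginal_rates <- function(strata) {
  validate_strata(strata)
  key <- interaction(strata$sex, strata$age_band, drop = TRUE, sep = "|")
  ex <- rowsum(strata$examinees, key)
  ca <- rowsum(strata$cases, key)
  lev <- rownames(ex)
  parts <- strsplit(lev, "|", fixed = TRUE)
  out <- data.frame(sex = vapply(parts, `[[`, "", 1L),
                    age_band = vapply(parts, `[[`, "", 2L),
                    examinees = ex[, 1L], cases = ca[, 1L],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (any(out$cases > 0 & out$examinees == 0))
    abort("stratum with cases but zero examinees")
  out$rate <- ifelse(out$examinees > 0, out$cases / out$examinees, 0)
  out
}

validate_strata <- function(strata) {
  if (!is.data.frame(strata)) abort("strata must be a data.frame")
  need <- c("region_id", "sex", "age_band", "examinees", "cases")
  if (!all(need %in% names(strata)))
    abort("strata must have columns %s", paste(need, collapse = ", "))
  check_count_vector(strata$examinees, "examinees")
  check_count_vector(strata$cases, "cases")
  invisible(strata)
}

#' Indirectly standardised expected counts and prevalence ratios
#'
#' For each region the sex- and age-adjusted expected number of cases is
#' \code{e_i = sum_k pop_ik * pr_k}, and the standardised prevalence ratio is
#' \code{spr_i = o_i / e_i}. When the stratum rates are computed internally
#' from the same table (the default) the expected counts conserve the case
#' total: \code{sum(e_i) = sum(o_i)}.
#'
#' @param strata long-format stratified table, see \code{\link{marginal_rates}}.
#' @param rates optional external reference rates (data.frame with
#'   \code{sex}, \code{age_band}, \code{rate}); by default the marginal rates
#'   of \code{strata} itself are used.
#' @return An \code{expected_table}: data.frame with columns
#'   \code{region_id}, \code{observed}, \code{expected}, \code{spr} (NA where
#'   \code{expected} is 0) and \code{spr_defined}; the rates used are attached
#'   as attribute \code{"rates"}. Regions appear in order of first appearance
#'   in \code{strata}.
#' @export
expected_counts <- function(strata, rates = NULL) {
  validate_strata(strata)
  internal <- is.null(rates)
  if (internal) rates <- marginal_rates(strata)
  if (!all(c("sex", "age_band", "rate") %in% names(rates)))
    abort("rates must have columns sex, age_band, rate")
  if (any(rates$rate < 0 | rates$rate > 1)) abort("rates must lie in [0, 1]")

  skey <- paste(strata$sex, strata$age_band, sep = "|")
  rkey <- paste(rates$sex, rates$age_band, sep = "|")
  pos <- match(skey, rkey)
  if (anyNA(pos))
    abort("no reference rate for stratum %s",
          paste(unique(skey[is.na(pos)]), collapse = ", "))
  rk <- rates$rate[pos]

  rid <- factor(as.character(strata$region_id),
                levels = unique(as.character(strata$region_id)))
  e <- rowsum(strata$examinees * rk, rid)[, 1L]
  o <- rowsum(strata$cases, rid)[, 1L]
  if (any(e == 0 & o > 0))
    warning("region with observed cases but zero expected; spr undefined")
  spr <- ifelse(e > 0, o / e, NA_real_)
  out <- data.frame(region_id = levels(rid), observed = as.numeric(o),
                    expected = as.numeric(e), spr = spr,
                    spr_defined = e > 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (internal) {
    tot_o <- sum(out$observed)
    if (tot_o > 0 &&
        abs(sum(out$expected) - tot_o) > 1e-10 * max(1, tot_o))
      abort("internal standardisation failed to conserve the case total")
  }
  attr(out, "rates") <- rates
  class(out) <- c("expected_table", "data.frame")
  out
}

#' Read a stratified counts table
#' @param path CSV with header \code{region_id,sex,age_band,examinees,cases}.
#' @return data.frame, validated.
#' @export
read_strata <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  validate_strata(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write an expected table to CSV
#' @param x an \code{expected_table}.
#' @param path output CSV path.
#' @export
write_expected <- function(x, path) {
  utils::write.csv(as.data.frame(x)[c("region_id", "observed", "expected",
                                      "spr")],
                   path, row.names = FALSE)
  invisible(path)
}
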