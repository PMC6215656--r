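#' Convert an effect estimate to a signed z-score
#'
#' The estimate is converted to a t statistic `U/s`, its two-sided p-value
#' taken with the stated degrees of freedom, mapped back to the equivalent
#' standard-normal quantile, and given the sign of the original effect:
#' \eqn{z = \mathrm{sign}(U)\,|\Phi^{-1}(p/2)|}. With large df this is the
#' identity up to the t-vs-normal correction; a zero effect maps to z = 0.
#'
#' @param U Signed effect estimate(s).
#' @param s Standard error(s), positive.
#' @param df Degrees of freedom of the t reference.
#' @return Signed z-score(s).
#' @export
signed_z <- function(U, s, df) {
  if (any(s <= 0)) stop("standard errors must be positive")
  p <- 2 * stats::pt(abs(U / s), df, lower.tail = FALSE)
  sign(U) * abs(stats::qnorm(p / 2))
}

#' Combine signed z-scores into an unweighted meta-analysis statistic
#'
#' \deqn{\bar z^* = \sqrt{(\sum_i z_i)^2 / n}}
#' which is approximately N(0,1) in magnitude under the joint null; the
#' two-sided p-value is taken from the standard normal. \eqn{\bar z^*} is
#' non-negative by construction, so the signed sum is returned alongside to
#' keep the direction recoverable.
#'
#' @param z Numeric vector of signed z-scores (length >= 1).
#' @return One-row data.frame `n`, `z_bar_star`, `signed_sum`, `p_meta`.
#' @export
combine_z <- function(z) {
  if (length(z) == 0) stop("cannot combine an empty set of z-scores")
  s <- sum(z)
  zb <- sqrt(s^2 / length(z))
  data.frame(n = length(z), z_bar_star = zb, signed_sum = s,
             p_meta = 2 * stats::pnorm(zb, lower.tail = FALSE))
}

#' Meta-analyze effect estimates across analyses or datasets
#'
#' Stacks estimate tables, converts each (effect, se, df) row to a signed
#' z-score and combines the z-scores per key with [combine_z()]. Effects
#' must already share one reference-allele orientation across analyses (the
#' scan functions provide `effect_ref` for this; ASE slopes and negated
#' eQTL slopes are both positive when the reference allele increases
#' expression). Keys present in only one table pass through with n = 1.
#'
#' @param tables List of data.frames, each with the `by` key columns plus
#'   `effect`, `se`, `df` (a `dataset` column is added from the list names
#'   when absent).
#' @param by Character vector of key column names, e.g.
#'   `c("dsnp_id", "tsnp_id")` or `c("dsnp_id", "gene_id")`.
#' @return Data.frame, one row per key: key columns, `n`, `z_bar_star`,
#'   `signed_sum`, `p_meta`. Row order follows the sorted keys, so the
#'   result is invariant to the order of the input tables.
#' @export
meta_analyze <- function(tables, by) {
  stopifnot(is.list(tables), length(tables) >= 1)
  stacked <- do.call(rbind, lapply(tables, function(t) {
    stopifnot(all(c(by, "effect", "se", "df") %in% names(t)))
    t[c(by, "effect", "se", "df")]
  }))
  key <- do.call(paste, c(stacked[by], sep = "\r"))
  z <- signed_z(stacked$effect, stacked$se, stacked$df)
  groups <- split(z, key)
  keys <- names(groups)
  res <- do.call(rbind, lapply(groups, combine_z))
  keycols <- stacked[match(keys, key), by, drop = FALSE]
  out <- cbind(keycols, res)
  out <- out[order(keys), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool result tables without combining evidence
#'
#' Concatenates the tables, preserving every original row (effects and
#' p-values untouched) and tagging each with its source, so a SNP tested in
#' several analyses keeps multiple solutions.
#'
#' @param tables Named list of data.frames with identical columns.
#' @return Single data.frame with a prepended `source` column.
#' @export
pool_analyses <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  nm <- names(tables)
  if (is.null(nm)) nm <- paste0("table", seq_along(tables))
  do.call(rbind, c(lapply(seq_along(tables), function(i) {
    cbind(data.frame(source = nm[i], stringsAsFactors = FALSE), tables[[i]])
  }), make.row.names = FALSE))
}
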