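# Class separability of feature distributions: Bhattacharyya distance
# between two univariate Gaussians and its bounded Jeffries-Matusita
# transform, per feature and aggregated per feature set.

#' Bhattacharyya distance between two univariate Gaussians
#'
#' `D_B = 1/4 log(1/4 (s_p/s_q + s_q/s_p + 2)) + 1/4 (mu_p - mu_q)^2 /
#' (s_p + s_q)` with `s` the variances. For equal variances this reduces to
#' `delta^2 / (8 sigma^2)`.
#'
#' @param mu_p,mu_q class means.
#' @param var_p,var_q class variances (strictly positive).
#' @param feature optional feature name used in error messages.
#' @return Non-negative distance.
#' @export
bhattacharyya_distance <- function(mu_p, mu_q, var_p, var_q,
                                   feature = NULL) {
  if (var_p <= 0 || var_q <= 0)
    stopf("zero or negative variance%s; Bhattacharyya distance undefined",
          if (is.null(feature)) "" else paste0(" for feature '", feature, "'"))
  0.25 * log(0.25 * (var_p / var_q + var_q / var_p + 2)) +
    0.25 * (mu_p - mu_q)^2 / (var_p + var_q)
}

#' Jeffries-Matusita distance from a Bhattacharyya distance
#'
#' `JM = 2 (1 - exp(-D_B))`, a strictly increasing map of `D_B` onto
#' \[0, 2): 0 for identical distributions, approaching 2 for fully
#' separated ones.
#'
#' @param d_b Bhattacharyya distance(s), non-negative.
#' @export
jm_distance <- function(d_b) {
  if (any(d_b < 0)) stopf("Bhattacharyya distance must be non-negative")
  2 * (1 - exp(-d_b))
}

#' Per-feature and aggregate JM separability of a feature table
#'
#' Treats each feature univariately: class-conditional means and variances
#' are estimated from the selected rows, converted to Bhattacharyya and JM
#' distances. The per-set scalar is the mean JM across features by default;
#' max and median are also returned.
#'
#' @param table feature table (data.frame with a `group` column).
#' @param feature_names columns to evaluate; defaults to
#'   `attr(table, "feature_names")`.
#' @param rows optional row subset (e.g. the training rows of a
#'   leave-one-subject-out dataset).
#' @param aggregate `"mean"` (default), `"max"` or `"median"` - which
#'   aggregate to report as `jm_aggregate`.
#' @return List with `per_feature` (data.frame: feature, d_b, jm),
#'   `jm_aggregate`, and all three aggregates `jm_mean`, `jm_max`,
#'   `jm_median`.
#' @export
featureset_jm <- function(table, feature_names = NULL, rows = NULL,
                          aggregate = c("mean", "max", "median")) {
  aggregate <- match.arg(aggregate)
  if (is.null(feature_names)) feature_names <- attr(table, "feature_names")
  if (is.null(feature_names))
    stopf("feature_names not given and not recorded on the table")
  if (!is.null(rows)) table <- table[rows, , drop = FALSE]
  groups <- unique(table$group)
  if (length(groups) != 2)
    stopf("both classes must be present (found: %s)",
          paste(groups, collapse = ", "))
  a <- table$group == groups[1]
  if (sum(a) < 2 || sum(!a) < 2) stopf("need >= 2 rows per class")
  per <- lapply(feature_names, function(fn) {
    x <- table[[fn]]
    d_b <- bhattacharyya_distance(mean(x[a]), mean(x[!a]),
                                  var(x[a]), var(x[!a]), feature = fn)
    data.frame(feature = fn, d_b = d_b, jm = jm_distance(d_b))
  })
  per <- do.call(rbind, per)
  out <- list(per_feature = per,
              jm_mean = mean(per$jm), jm_max = max(per$jm),
              jm_median = median(per$jm))
  out$jm_aggregate <- switch(aggregate, mean = out$jm_mean,
                             max = out$jm_max, median = out$jm_median)
  out
}
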