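#' Compare tortuosity distributions between two image groups
#'
#' Two-sample comparison of tau_net values, as used to contrast central
#' versus peripheral corneal neurite fields: the Kolmogorov-Smirnov
#' statistic `D = max |ECDF_a - ECDF_b|` with a two-sided p-value (exact
#' distribution when `length(a) * length(b) <= 1e4`, which covers typical
#' image-group sizes; asymptotic otherwise), the difference of group
#' medians, and the percent difference relative to the second (reference)
#' group's median.
#'
#' @param a,b numeric vectors of tau_net values, each of length >= 3.
#'   `b` is the reference group for the percent difference.
#' @return A [GroupComparison-class].
#' @examples
#' compareGroups(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))  # D = 1, p = 0.1
#' @export
compareGroups <- function(a, b) {
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 values")
  exact <- length(a) * length(b) <= 1e4
  ks <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  dm <- stats::median(a) - stats::median(b)
  new("GroupComparison",
      deltaMedian = dm,
      percentDifference = 100 * dm / stats::median(b),
      ksStatistic = unname(ks$statistic),
      pValue = min(max(ks$p.value, 0), 1),
      nA = length(a), nB = length(b))
}
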