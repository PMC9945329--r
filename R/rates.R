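#' Predict the midpoint unfolding rate constant from LRO
#'
#' Empirical correlation for two-state beta-sheet proteins at the
#' denaturation midpoint: log10(ku / s^-1) = -1.70 * LRO + 6.6. The
#' correlation was calibrated at the transition midpoint (where folded and
#' unfolded states are equally stable) and should only be applied there.
#'
#' @param lro Long-range order (dimensionless, >= 0).
#' @return Unfolding rate constant ku at the midpoint, s^-1.
#' @export
ku_from_lro <- function(lro) {
  stopifnot(all(lro >= 0))
  10^(-1.70 * lro + 6.6)
}

#' Predict the midpoint unfolding rate constant from ACO
#'
#' Companion correlation to [ku_from_lro()]:
#' log10(ku / s^-1) = -0.52 * ACO + 5.9.
#'
#' @param aco Absolute contact order (dimensionless, >= 0).
#' @return Unfolding rate constant ku at the midpoint, s^-1.
#' @export
ku_from_aco <- function(aco) {
  stopifnot(all(aco >= 0))
  10^(-0.52 * aco + 5.9)
}

#' Predicted fold change in unfolding rate between two topologies
#'
#' Under a log-linear correlation with slope `slope` per metric unit, the
#' ratio ku(a) / ku(b) is 10^(slope * (metric_b - metric_a)): a protein with
#' the larger metric unfolds more slowly.
#'
#' @param metric_a,metric_b Metric values (LRO or ACO) for the two proteins.
#' @param slope Magnitude of the correlation slope: 1.70 for LRO, 0.52 for
#'   ACO.
#' @return Predicted ratio ku(a) / ku(b).
#' @export
fold_change <- function(metric_a, metric_b, slope) {
  10^(slope * (metric_b - metric_a))
}

#' Half-life of unfolding
#'
#' @param ku Unfolding rate constant, s^-1 (> 0).
#' @param unit Output unit: `"s"`, `"min"`, `"h"`, or `"yr"`.
#' @return ln(2) / ku converted to `unit`.
#' @export
half_life <- function(ku, unit = c("s", "min", "h", "yr")) {
  unit <- match.arg(unit)
  stopifnot(all(ku > 0))
  secs <- log(2) / ku
  switch(unit,
         s = secs,
         min = secs / 60,
         h = secs / 3600,
         yr = secs / (365.25 * 24 * 3600))
}

#' Rate predictions from a topology report
#'
#' @param report A `topology_report`, or `NULL` if raw values are supplied.
#' @param lro,aco Optional raw metric values overriding the report.
#' @return data.frame with one row per metric: `source_metric`,
#'   `metric_value`, `ku_cmid` (s^-1), `half_life_min`.
#' @export
predict_rates <- function(report = NULL, lro = NULL, aco = NULL) {
  if (!is.null(report)) {
    stopifnot(inherits(report, "topology_report"))
    if (is.null(lro)) lro <- report$lro
    if (is.null(aco)) aco <- report$aco
  }
  rows <- list()
  if (!is.null(lro)) {
    ku <- ku_from_lro(lro)
    rows[[length(rows) + 1L]] <- data.frame(
      source_metric = "LRO", metric_value = lro, ku_cmid = ku,
      half_life_min = half_life(ku, "min"))
  }
  if (!is.null(aco)) {
    ku <- ku_from_aco(aco)
    rows[[length(rows) + 1L]] <- data.frame(
      source_metric = "ACO", metric_value = aco, ku_cmid = ku,
      half_life_min = half_life(ku, "min"))
  }
  if (!length(rows)) stop("supply a topology_report or lro/aco values")
  do.call(rbind, rows)
}
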