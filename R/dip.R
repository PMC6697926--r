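#' Hartigan's dip statistic
#'
#' Computes the dip statistic of a numeric sample: the smallest sup-norm
#' distance between the empirical CDF and any unimodal CDF (one that is
#' convex below its mode and concave above it, with an atom permitted at the
#' mode). Large values flag multimodality. Here it screens CpG probes whose
#' beta values split into several modes across a cohort -- the signature of
#' a tumor--stroma admixture at probes where the two compartments disagree.
#'
#' The statistic always lies in `[1/(2n), 0.25]`: the lower bound is the
#' ECDF jump at a data point (attained by e.g. equally spaced values), the
#' upper bound is attained by a balanced two-point mass. Ties are retained;
#' a constant sample returns the floor `1/(2n)`. The dip is invariant under
#' positive affine transforms and under reflection of the sample.
#'
#' @param x Numeric vector, at least 2 finite values (ties allowed).
#' @return The dip statistic, a single number in `[1/(2n), 0.25]`.
#' @examples
#' dip_statistic(c(0, 1))                  # 0.25
#' dip_statistic(seq(0, 0.9, by = 0.1))    # 1/(2*10) = 0.05
#' dip_statistic(rep(c(0.1, 0.9), 50))     # 0.25, balanced two-point mass
#' @export
dip_statistic <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) {
    stop("dip statistic requires at least 2 values, got ", length(x))
  }
  if (!all(is.finite(x))) {
    stop("dip statistic requires finite values; found NA/NaN/Inf")
  }
  .dip_sorted(sort(x))
}

#' Construct a probe ranking
#'
#' Orders probes by a screening statistic (dip, SD, or forest importance),
#' descending, with ties broken by probe id so rankings are reproducible.
#'
#' @param probe_id Probe identifiers.
#' @param statistic Per-probe score, same length.
#' @param method One of `"DIP"`, `"SD"`, `"IMPORTANCE"`.
#' @return A `probe_ranking` tibble with columns `probe_id`, `statistic`,
#'   `rank`, `method`.
#' @export
new_probe_ranking <- function(probe_id, statistic, method) {
  method <- match.arg(method, c("DIP", "SD", "IMPORTANCE"))
  out <- tibble::tibble(probe_id = as.character(probe_id),
                        statistic = as.numeric(statistic))
  # deterministic order: statistic descending, probe_id ascending on ties
  out <- out[order(-out$statistic, out$probe_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$method <- method
  class(out) <- c("probe_ranking", class(out))
  out
}

rank_probes_stat <- function(m, min_samples, stat_fun, method) {
  validate_beta_matrix(m)
  if (min_samples < 2) stop("min_samples must be at least 2")
  n_obs <- rowSums(!is.na(m))
  keep <- n_obs >= min_samples
  if (!any(keep)) {
    stop("no probe has at least ", min_samples, " non-missing values")
  }
  stats <- vapply(which(keep), function(i) {
    v <- m[i, ]
    stat_fun(v[!is.na(v)])
  }, numeric(1))
  r <- new_probe_ranking(rownames(m)[keep], stats, method)
  attr(r, "excluded_probes") <- rownames(m)[!keep]
  attr(r, "min_samples") <- min_samples
  r
}

#' Rank probes by multimodality (dip statistic)
#'
#' Computes the dip statistic of every probe's beta values across samples
#' and returns the probes ranked by it, most multimodal first. Missing
#' values are dropped per probe; probes with fewer than `min_samples`
#' non-missing values are excluded and listed in the `excluded_probes`
#' attribute of the result.
#'
#' @param m Beta matrix (probes x samples), see [read_beta_matrix()].
#' @param min_samples Minimum non-missing values a probe needs to be ranked.
#'   The dip of very small samples is pinned near its bounds, so the default
#'   asks for 10.
#' @return A `probe_ranking` tibble with columns `probe_id`, `statistic`,
#'   `rank`, `method`; ordered by statistic descending, ties broken by
#'   probe id.
#' @seealso [rank_probes_by_sd()], [select_top_fraction()]
#' @export
rank_probes_by_dip <- function(m, min_samples = 10) {
  rank_probes_stat(m, min_samples, dip_statistic, "DIP")
}

#' Rank probes by standard deviation
#'
#' The variance-screening comparator to [rank_probes_by_dip()]: probes are
#' ranked by the sample standard deviation (denominator n-1) of their beta
#' values. Same missing-value and `min_samples` handling as the dip ranking.
#'
#' @inheritParams rank_probes_by_dip
#' @return A `probe_ranking` tibble, method `"SD"`.
#' @export
rank_probes_by_sd <- function(m, min_samples = 10) {
  rank_probes_stat(m, min_samples, stats::sd, "SD")
}

#' Select the top fraction of a probe ranking
#'
#' Returns the first `ceiling(fraction * nrow(r))` probe ids of a ranking.
#' The ceiling rule never returns an empty set for a positive fraction, and
#' the ranking's deterministic tie rule makes the selection reproducible.
#'
#' @param r A `probe_ranking` from one of the `rank_probes_*` functions.
#' @param fraction Fraction in `(0, 1]` of probes to keep.
#' @return Character vector of probe ids, in ranking order.
#' @export
select_top_fraction <- function(r, fraction) {
  if (!is.data.frame(r) || !all(c("probe_id", "statistic") %in% names(r))) {
    stop("`r` must be a probe_ranking (see rank_probes_by_dip)")
  }
  if (nrow(r) == 0) stop("ranking is empty")
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      is.na(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must be a single value in (0, 1], got ", fraction)
  }
  k <- ceiling(fraction * nrow(r))
  r$probe_id[seq_len(k)]
}

#' Write a probe ranking to TSV
#'
#' @param r A `probe_ranking` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_probe_ranking <- function(r, path) {
  readr::write_tsv(r[, c("probe_id", "statistic", "method", "rank")], path)
  invisible(path)
}
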