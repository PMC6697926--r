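#' LUMP immune-hypomethylation purity score
#'
#' Averages the beta values of a panel of CpGs hypomethylated in
#' leukocytes (44 probes in the published panel): in a pure tumor these
#' sites are methylated, and immune/stromal infiltration pulls the mean
#' down. The mean is divided by `scale` (0.85 in the published score) and
#' capped at 1. The panel itself is supplied by the user, one probe id per
#' line; a synthetic placeholder panel ships with the simulator.
#'
#' @param m Beta matrix (probes x samples).
#' @param panel Character vector of panel probe ids; at least one must be
#'   present in `m`.
#' @param scale Divisor applied to the mean panel beta, default 0.85.
#' @param cap Cap scores at 1 (default). With `cap = FALSE` the raw scaled
#'   mean is returned.
#' @return A purity tibble, source `LUMP`, with a `n_panel_probes` column
#'   (per-sample count of present, non-missing panel probes); the panel
#'   probes used are in attribute `panel_used`.
#' @export
lump_score <- function(m, panel, scale = 0.85, cap = TRUE) {
  validate_beta_matrix(m)
  if (length(panel) == 0) stop("LUMP panel is empty")
  present <- intersect(panel, rownames(m))
  if (length(present) == 0) {
    stop("no panel probe is present in the beta matrix")
  }
  sub <- m[present, , drop = FALSE]
  score <- colMeans(sub, na.rm = TRUE) / scale
  if (cap) score <- pmin(score, 1)
  out <- new_purity_table(colnames(m), score, "LUMP")
  out$n_panel_probes <- unname(colSums(!is.na(sub)))
  attr(out, "panel_used") <- present
  out
}

intersect_purities <- function(a, b) {
  validate_purity_table(a)
  validate_purity_table(b)
  shared <- intersect(a$sample_id, b$sample_id)
  list(shared = shared,
       a = a$purity[match(shared, a$sample_id)],
       b = b$purity[match(shared, b$sample_id)])
}

#' Compare two purity tables
#'
#' Computes, on the intersection of the two sample sets, the Pearson
#' correlation, the mean squared error and the median absolute difference
#' between the two purity vectors -- the summary used to judge how well a
#' trained model reproduces its gold standard.
#'
#' @param a,b Purity tibbles sharing at least 3 samples.
#' @return A one-row `purity_evaluation` tibble: `source_a`, `source_b`,
#'   `n`, `pearson_r`, `mse`, `median_abs_diff`. If either vector has zero
#'   variance, `pearson_r` is `NA` and `r_undefined` is `TRUE`; MSE is
#'   still returned. The paired values are kept in attribute `pairs` for
#'   plotting.
#' @export
evaluate_predictions <- function(a, b) {
  z <- intersect_purities(a, b)
  if (length(z$shared) < 3) {
    stop("need at least 3 shared samples, got ", length(z$shared))
  }
  undef <- stats::var(z$a) == 0 || stats::var(z$b) == 0
  r <- if (undef) NA_real_ else stats::cor(z$a, z$b)
  out <- tibble::tibble(
    source_a = a$source[1], source_b = b$source[1],
    n = length(z$shared),
    pearson_r = r,
    mse = mean((z$a - z$b)^2),
    median_abs_diff = stats::median(abs(z$a - z$b)),
    r_undefined = undef
  )
  attr(out, "pairs") <- tibble::tibble(sample_id = z$shared,
                                       purity_a = z$a, purity_b = z$b)
  class(out) <- c("purity_evaluation", class(out))
  out
}

#' Pairwise Pearson correlations between purity tables
#'
#' Each cell is computed on that pair's own sample intersection; pairs
#' sharing fewer than 3 samples are flagged `NA`.
#'
#' @param tables Named list of purity tibbles (names default to each
#'   table's source tag).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlations <- function(tables) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- vapply(tables, function(t) t$source[1], "")
  }
  if (anyDuplicated(names(tables))) {
    stop("tables need unique names (several share a source tag)")
  }
  k <- length(tables)
  out <- diag(1, k)
  dimnames(out) <- list(names(tables), names(tables))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      z <- intersect_purities(tables[[i]], tables[[j]])
      r <- if (length(z$shared) < 3 || stats::var(z$a) == 0 ||
               stats::var(z$b) == 0) NA_real_ else stats::cor(z$a, z$b)
      out[i, j] <- out[j, i] <- r
    }
  }
  out
}

#' Per-group purity quantiles
#'
#' Empirical quantiles of purity per entity / subgroup, with linear
#' interpolation between order statistics -- the per-entity reference
#' tables from which low-purity cut-offs can be read.
#'
#' @param p Purity tibble with a `group` column.
#' @param probs Quantile probabilities, sorted, strictly inside `(0, 1)`.
#' @return A `quantile_table` tibble: one row per group x probability with
#'   columns `group`, `n`, `prob`, `purity`; groups with fewer than 3
#'   samples are flagged in the `small_group` column.
#' @export
purity_quantiles_by_group <- function(p, probs = c(0.05, 0.25, 0.50, 0.75, 0.95)) {
  validate_purity_table(p)
  if (!"group" %in% names(p) || all(is.na(p$group))) {
    stop("purity table has no group labels")
  }
  if (any(probs <= 0 | probs >= 1) || is.unsorted(probs, strictly = TRUE)) {
    stop("probs must be strictly increasing and inside (0, 1)")
  }
  out <- p |>
    dplyr::group_by(.data$group) |>
    dplyr::reframe(n = dplyr::n(),
                   prob = probs,
                   purity = stats::quantile(.data$purity, probs = probs,
                                            type = 7, names = FALSE)) |>
    dplyr::mutate(small_group = .data$n < 3) |>
    dplyr::arrange(.data$group, .data$prob)
  class(out) <- c("quantile_table", class(out))
  out
}

#' Summary of absolute purity differences
#'
#' Distribution of `|a - b|` over the shared samples of two purity tables:
#' median, mean, maximum, and histogram bin counts.
#'
#' @param a,b Purity tibbles sharing at least 1 sample.
#' @param bin_width Histogram bin width on the absolute-difference scale.
#' @return A list with elements `n`, `median`, `mean`, `max`, and
#'   `histogram` (tibble of bin midpoints and counts).
#' @export
abs_difference_summary <- function(a, b, bin_width = 0.01) {
  z <- intersect_purities(a, b)
  if (length(z$shared) == 0) stop("no shared samples")
  d <- abs(z$a - z$b)
  breaks <- seq(0, ceiling(max(d, bin_width) / bin_width) * bin_width,
                by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  list(n = length(d),
       median = stats::median(d),
       mean = mean(d),
       max = max(d),
       histogram = tibble::tibble(midpoint = h$mids, count = h$counts))
}

#' Plot a purity evaluation
#'
#' Scatter of the two purity vectors on their shared samples with the
#' identity line, annotated with Pearson r.
#'
#' @param object A `purity_evaluation` from [evaluate_predictions()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.purity_evaluation <- function(object, ...) {
  pairs <- attr(object, "pairs")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$purity_a, y = .data$purity_b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.5, color = "steelblue") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = object$source_a, y = object$source_b,
                  title = sprintf("r = %.3f, MSE = %.4f (n = %d)",
                                  object$pearson_r, object$mse, object$n)) +
    ggplot2::theme_minimal()
}

#' Plot per-group purity distributions
#'
#' @param p Purity tibble with a `group` column.
#' @return A ggplot of per-group purity boxplots.
#' @export
plot_purity_by_group <- function(p) {
  validate_purity_table(p)
  if (!"group" %in% names(p)) stop("purity table has no group labels")
  ggplot2::ggplot(p, ggplot2::aes(x = .data$group, y = .data$purity)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.5,
                          outlier.alpha = 0.4) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "tumor purity") +
    ggplot2::theme_minimal()
}
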