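#' Training configuration for the purity model
#'
#' @param screening_method Probe screening statistic, `"DIP"` (default,
#'   multimodality) or `"SD"` (variance comparator).
#' @param screening_fraction Fraction of screened probes kept, default 0.20
#'   (the top 20% most multimodal probes).
#' @param sweep_fractions Candidate model sizes for the second step, as
#'   fractions of the screened probe set. With the default 0.20 screening
#'   of a full 428,000-probe 450K array the 1% candidate is the 856-probe
#'   model size.
#' @param n_trees Trees per forest, all stages.
#' @param train_fraction Nominal training share of the labeled samples.
#' @param min_samples Minimum non-missing values per probe for screening.
#' @param seed Master seed for partitioning and all forests.
#' @return A `purity_config` list.
#' @export
purity_config <- function(screening_method = c("DIP", "SD"),
                          screening_fraction = 0.20,
                          sweep_fractions = c(0.001, 0.01, 0.05, 0.10),
                          n_trees = 500,
                          train_fraction = 0.70,
                          min_samples = 10,
                          seed = 1) {
  cfg <- list(screening_method = match.arg(screening_method),
              screening_fraction = screening_fraction,
              sweep_fractions = sort(sweep_fractions),
              n_trees = n_trees,
              train_fraction = train_fraction,
              min_samples = min_samples,
              seed = seed)
  if (cfg$screening_fraction <= 0 || cfg$screening_fraction > 1) {
    stop("screening_fraction must lie in (0, 1]")
  }
  if (any(cfg$sweep_fractions <= 0 | cfg$sweep_fractions > 1)) {
    stop("sweep_fractions must lie in (0, 1]")
  }
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)")
  }
  if (cfg$n_trees < 1) stop("n_trees must be positive")
  class(cfg) <- "purity_config"
  cfg
}

#' Stratified train/test partition of labeled samples
#'
#' Splits the labeled samples into a training set (nominally
#' `train_fraction` of them, default 70%) and a test set, reproducibly for
#' a fixed seed. When the purity table carries a `group` column the split
#' is stratified on it, so every entity is proportionally represented in
#' both sets; otherwise samples are stratified on outcome quintile bins.
#' A stratum with a single sample triggers a pooled (unstratified) split
#' and a `pooled_fallback` flag on the result.
#'
#' @param labels Purity tibble (see [read_purity_table()]).
#' @param train_fraction Nominal training share, in `(0, 1)`.
#' @param seed Integer seed.
#' @return A `sample_partition` tibble with columns `sample_id`, `set`
#'   (`"train"` / `"test"`) and `stratum`; attributes `train_fraction`,
#'   `stratify_on`, `pooled_fallback`.
#' @export
partition_samples <- function(labels, train_fraction = 0.70, seed = 1) {
  validate_purity_table(labels)
  if (nrow(labels) < 2) stop("need at least 2 labeled samples to partition")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)")
  }

  if ("group" %in% names(labels) && !all(is.na(labels$group))) {
    stratum <- as.character(labels$group)
    stratify_on <- "group"
  } else {
    brk <- unique(stats::quantile(labels$purity, probs = seq(0, 1, 0.2),
                                  names = FALSE))
    if (length(brk) < 2) {
      stratum <- rep("all", nrow(labels))
    } else {
      stratum <- as.character(cut(labels$purity, breaks = brk,
                                  include.lowest = TRUE))
    }
    stratify_on <- "outcome-bins"
  }

  pooled_fallback <- FALSE
  if (min(table(stratum)) < 2) {
    pooled_fallback <- TRUE
    stratum <- rep("all", nrow(labels))
    stratify_on <- "none"
    warning("a stratum had a single sample; falling back to a pooled split")
  }

  set <- rep("test", nrow(labels))
  withr::with_seed(seed, {
    for (s in sort(unique(stratum))) {
      idx <- which(stratum == s)
      n_train <- round(train_fraction * length(idx))
      n_train <- max(1, min(length(idx) - 1, n_train))
      set[sample(idx, n_train)] <- "train"
    }
  })

  out <- tibble::tibble(sample_id = labels$sample_id, set = set,
                        stratum = stratum)
  attr(out, "train_fraction") <- train_fraction
  attr(out, "stratify_on") <- stratify_on
  attr(out, "pooled_fallback") <- pooled_fallback
  attr(out, "seed") <- seed
  class(out) <- c("sample_partition", class(out))
  out
}

# samples x probes design matrix from a probes x samples beta matrix
design_matrix <- function(m, probes, samples) {
  missing_p <- setdiff(probes, rownames(m))
  if (length(missing_p)) {
    stop("probes absent from the beta matrix: ",
         paste(utils::head(missing_p, 5), collapse = ", "))
  }
  t(m[probes, samples, drop = FALSE])
}

fit_forest <- function(x, y, n_trees, seed, importance = "none") {
  ranger::ranger(x = x, y = y, num.trees = n_trees, importance = importance,
                 seed = seed %% .Machine$integer.max, num.threads = 1,
                 oob.error = TRUE)
}

#' First random-forest step: importance ranking of screened probes
#'
#' Fits a 500-tree (by default) regression forest of purity on the
#' screened probes and returns the probes ranked by the forest's built-in
#' impurity-decrease (node-variance-reduction) importance; permutation
#' importance is available by flag. This step exists purely to shrink the
#' probe set for the candidate sweep.
#'
#' @param x Beta matrix restricted to the screened probes (probes x
#'   samples), complete (no missing values).
#' @param y Purity tibble covering `colnames(x)`.
#' @param n_trees Trees, default 500.
#' @param seed Integer seed.
#' @param importance `"impurity"` (default) or `"permutation"`.
#' @return A `probe_ranking` tibble, method `"IMPORTANCE"`. A zero-variance
#'   outcome is flagged in attribute `zero_variance_outcome`.
#' @export
train_initial_forest <- function(x, y, n_trees = 500, seed = 1,
                                 importance = c("impurity", "permutation")) {
  importance <- match.arg(importance)
  validate_purity_table(y)
  if (!all(colnames(x) %in% y$sample_id)) {
    stop("samples in `x` missing from the label table: ",
         paste(utils::head(setdiff(colnames(x), y$sample_id), 5), collapse = ", "))
  }
  if (ncol(x) < 2) stop("need at least 2 training samples")
  if (anyNA(x)) stop("beta matrix passed to the forest contains missing values")
  yv <- y$purity[match(colnames(x), y$sample_id)]
  zero_var <- stats::var(yv) == 0
  if (zero_var) warning("outcome has zero variance; importances are degenerate")
  rf <- fit_forest(t(x), yv, n_trees, seed, importance = importance)
  r <- new_probe_ranking(rownames(x), ranger::importance(rf), "IMPORTANCE")
  attr(r, "zero_variance_outcome") <- zero_var
  attr(r, "oob_mse") <- rf$prediction.error
  r
}

#' Candidate probe counts from fractions of the screened set
#'
#' The candidate model sizes are taken as fractions of the screened probe
#' set, rounded up. For a full 450K array (428,000 usable probes) screened
#' to its top 20% (85,600 probes), the defaults give candidates of 86,
#' 856, 4,280 and 8,560 probes -- the 1% candidate being the 856-probe
#' model size.
#'
#' @param n_screened Number of screened (ranked) probes.
#' @param fractions Candidate fractions in `(0, 1]`.
#' @return Integer vector of strictly increasing probe counts.
#' @export
candidate_probe_counts <- function(n_screened,
                                   fractions = c(0.001, 0.01, 0.05, 0.10)) {
  if (n_screened < 1) stop("n_screened must be positive")
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must lie in (0, 1]")
  counts <- as.integer(ceiling(sort(fractions) * n_screened))
  if (any(counts < 1)) stop("a candidate rounds to zero probes")
  if (anyDuplicated(counts)) {
    stop("candidate fractions collapse to duplicate probe counts: ",
         paste(counts, collapse = ", "))
  }
  counts
}

#' Candidate-size sweep with out-of-bag model selection
#'
#' For each fraction of the screened probe set (default 0.1, 1, 5 and 10%),
#' fits a forest on the top `ceiling(fraction * n)` probes by importance
#' and records the mean-squared out-of-bag error -- each training sample
#' predicted only by trees whose bootstrap excluded it. The chosen
#' candidate minimizes the OOB error; ties go to the smallest probe count.
#'
#' @param x Beta matrix restricted to the screened probes (probes x
#'   samples), complete.
#' @param y Purity tibble covering `colnames(x)`.
#' @param importance A `probe_ranking` (method `IMPORTANCE`) covering the
#'   probes of `x`.
#' @param fractions Candidate fractions of the screened set, in `(0, 1]`.
#' @param n_trees Trees per candidate forest.
#' @param seed Integer seed.
#' @return A `candidate_sweep` tibble with columns `fraction`, `n_probes`,
#'   `oob_mse`, `chosen`.
#' @export
sweep_candidates <- function(x, y, importance,
                             fractions = c(0.001, 0.01, 0.05, 0.10),
                             n_trees = 500, seed = 1) {
  validate_purity_table(y)
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must lie in (0, 1]")
  fractions <- sort(fractions)
  if (!all(rownames(x) %in% importance$probe_id)) {
    stop("importance ranking does not cover all probes of `x`")
  }
  counts <- candidate_probe_counts(nrow(importance), fractions)
  yv <- y$purity[match(colnames(x), y$sample_id)]
  oob <- vapply(seq_along(counts), function(i) {
    probes <- importance$probe_id[seq_len(counts[i])]
    rf <- fit_forest(design_matrix(x, probes, colnames(x)), yv, n_trees,
                     seed + i)
    rf$prediction.error
  }, numeric(1))
  chosen <- which.min(oob)  # counts ascending, so ties pick the smallest
  out <- tibble::tibble(fraction = fractions, n_probes = as.integer(counts),
                        oob_mse = oob,
                        chosen = seq_along(counts) == chosen)
  class(out) <- c("candidate_sweep", class(out))
  out
}

#' Train a purity model
#'
#' The end-to-end two-step pipeline: stratified 70/30 partition of the
#' labeled samples; probe screening on the training partition only (top
#' 20% by dip statistic by default -- the test partition never influences
#' probe selection); a first 500-tree forest whose importance ranking
#' shrinks the probe set; a candidate-size sweep selected by out-of-bag
#' error; and a final forest refit on the chosen probe set. Probes with
#' any missing value across the training samples are dropped before
#' screening.
#'
#' @param m Beta matrix (probes x samples).
#' @param labels Purity tibble; samples are intersected with `colnames(m)`.
#' @param config A [purity_config()].
#' @param partition Optional `sample_partition` (see [partition_samples()])
#'   fixing the train/test assignment, e.g. to retrain on exactly the same
#'   training samples after removing the held-out data. Samples of the
#'   partition absent from the input are ignored; by default a fresh
#'   stratified partition is drawn from the config seed.
#' @return A `purity_model` object carrying the final probe set, the
#'   fitted ensemble, the screening record, the full candidate sweep, the
#'   held-out test sample ids, the training-median imputation values, and
#'   the configuration. See [predict_purity()], [tidy.purity_model()],
#'   [glance.purity_model()].
#' @export
train_purity_model <- function(m, labels, config = purity_config(),
                               partition = NULL) {
  validate_beta_matrix(m)
  validate_purity_table(labels)
  if (!inherits(config, "purity_config")) stop("`config` must be a purity_config")
  if (nrow(labels) == 0) stop("label table is empty")

  labels <- labels[labels$sample_id %in% colnames(m), , drop = FALSE]
  if (nrow(labels) < 4) {
    stop("need at least 4 labeled samples present in the beta matrix, got ",
         nrow(labels))
  }
  seeds <- stage_seeds(config$seed, 4)

  if (is.null(partition)) {
    part <- partition_samples(labels, config$train_fraction, seed = seeds[1])
  } else {
    if (!all(c("sample_id", "set") %in% names(partition))) {
      stop("`partition` must have columns sample_id and set")
    }
    part <- partition[partition$sample_id %in% labels$sample_id, , drop = FALSE]
    if (!any(part$set == "train")) stop("partition leaves no training samples")
  }
  train_ids <- part$sample_id[part$set == "train"]
  test_ids <- part$sample_id[part$set == "test"]

  xtrain <- m[, train_ids, drop = FALSE]
  complete <- rowSums(is.na(xtrain)) == 0
  n_dropped <- sum(!complete)
  if (!any(complete)) stop("every probe has missing values in the training set")
  xtrain <- xtrain[complete, , drop = FALSE]

  screening_rank <- switch(config$screening_method,
    DIP = rank_probes_by_dip(xtrain, min_samples = config$min_samples),
    SD = rank_probes_by_sd(xtrain, min_samples = config$min_samples))
  screened <- select_top_fraction(screening_rank, config$screening_fraction)

  ytrain <- labels[labels$sample_id %in% train_ids, , drop = FALSE]
  xs <- xtrain[screened, , drop = FALSE]
  imp <- train_initial_forest(xs, ytrain, n_trees = config$n_trees,
                              seed = seeds[2])
  sweep <- sweep_candidates(xs, ytrain, imp,
                            fractions = config$sweep_fractions,
                            n_trees = config$n_trees, seed = seeds[3])
  final_probes <- imp$probe_id[seq_len(sweep$n_probes[sweep$chosen])]

  yv <- ytrain$purity[match(train_ids, ytrain$sample_id)]
  final_rf <- fit_forest(design_matrix(xtrain, final_probes, train_ids), yv,
                         config$n_trees, seeds[4], importance = "impurity")
  medians <- apply(xtrain[final_probes, , drop = FALSE], 1, stats::median)

  model <- list(
    final_probes = final_probes,
    ensemble = final_rf,
    screening = list(method = config$screening_method,
                     fraction = config$screening_fraction,
                     n_ranked = nrow(screening_rank),
                     n_selected = length(screened),
                     n_dropped_missing = n_dropped,
                     excluded_probes = attr(screening_rank, "excluded_probes")),
    candidate_record = sweep,
    selected_candidate = which(sweep$chosen),
    importance = imp,
    label_source = labels$source[1],
    seed = config$seed,
    version = MODEL_FORMAT_VERSION,
    partition = part,
    train_ids = train_ids,
    test_ids = test_ids,
    probe_medians = medians,
    oob_mse = final_rf$prediction.error,
    config = config
  )
  class(model) <- "purity_model"
  model
}

#' Predict tumor purity for new samples
#'
#' Applies a trained model to a beta matrix: per-sample mean of the tree
#' predictions, truncated into `[0, 1]`. Model probes absent from the
#' matrix -- and missing cells -- are imputed with the training-set median
#' stored in the model; the per-sample fraction of imputed probes is
#' returned in the `imputed_fraction` column.
#'
#' @param model A `purity_model`.
#' @param m Beta matrix (probes x samples); must contain at least one of
#'   the model's probes. Samples need not overlap the training set.
#' @return A purity tibble, source `RF_PREDICTED`, with an
#'   `imputed_fraction` column.
#' @export
predict_purity <- function(model, m) {
  if (!inherits(model, "purity_model")) stop("`model` is not a purity_model")
  validate_beta_matrix(m)
  present <- intersect(model$final_probes, rownames(m))
  if (length(present) == 0) {
    stop("none of the model's ", length(model$final_probes),
         " probes are present in the beta matrix")
  }
  x <- matrix(rep(model$probe_medians, ncol(m)),
              nrow = length(model$final_probes),
              dimnames = list(model$final_probes, colnames(m)))
  x[present, ] <- m[present, , drop = FALSE]
  imputed <- is.na(x)
  x[imputed] <- rep(model$probe_medians, ncol(m))[imputed]
  n_absent <- length(model$final_probes) - length(present)
  imputed_fraction <- (colSums(imputed) + n_absent) / length(model$final_probes)

  pred <- stats::predict(model$ensemble, data = t(x),
                         num.threads = 1)$predictions
  pred <- pmin(pmax(pred, 0), 1)
  out <- new_purity_table(colnames(m), pred, "RF_PREDICTED")
  out$imputed_fraction <- unname(imputed_fraction)
  out
}

#' @export
print.purity_model <- function(x, ...) {
  cat("purity_model (", x$label_source, "-trained)\n", sep = "")
  cat("  screening : top ", x$screening$fraction * 100, "% of ",
      x$screening$n_ranked, " probes by ", x$screening$method, "\n", sep = "")
  cat("  final     : ", length(x$final_probes), " probes, OOB MSE ",
      signif(x$oob_mse, 4), "\n", sep = "")
  cat("  samples   : ", length(x$train_ids), " train / ",
      length(x$test_ids), " test\n", sep = "")
  invisible(x)
}

#' Tidy the probe-level content of a purity model
#'
#' @param x A `purity_model`.
#' @param ... Unused.
#' @return One row per final model probe: `probe_id`, `importance` (from
#'   the first-step ranking), `rank`, `in_final_model`.
#' @export
tidy.purity_model <- function(x, ...) {
  out <- x$importance[, c("probe_id", "statistic", "rank")]
  names(out)[2] <- "importance"
  out$in_final_model <- out$probe_id %in% x$final_probes
  tibble::as_tibble(out)
}

#' One-row summary of a purity model
#'
#' @param x A `purity_model`.
#' @param ... Unused.
#' @return A one-row tibble: label source, screening method and fraction,
#'   probe counts at each stage, chosen candidate, OOB error, sample
#'   counts, seed.
#' @export
glance.purity_model <- function(x, ...) {
  tibble::tibble(
    label_source = x$label_source,
    screening_method = x$screening$method,
    screening_fraction = x$screening$fraction,
    n_probes_ranked = x$screening$n_ranked,
    n_probes_screened = x$screening$n_selected,
    n_probes_final = length(x$final_probes),
    oob_mse = x$oob_mse,
    n_train = length(x$train_ids),
    n_test = length(x$test_ids),
    seed = x$seed
  )
}

#' Plot the candidate sweep of a purity model
#'
#' Out-of-bag mean-squared error against candidate probe-set size, the
#' selected model highlighted.
#'
#' @param object A `purity_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.purity_model <- function(object, ...) {
  sw <- object$candidate_record
  ggplot2::ggplot(sw, ggplot2::aes(x = .data$n_probes, y = .data$oob_mse)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$chosen), size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40",
                                           `TRUE` = "firebrick"),
                                guide = "none") +
    ggplot2::labs(x = "candidate probe count (log scale)",
                  y = "out-of-bag MSE",
                  title = "Candidate-size sweep",
                  subtitle = paste0("chosen: ",
                                    sw$n_probes[sw$chosen], " probes")) +
    ggplot2::theme_minimal()
}

#' Plot a probe ranking
#'
#' Distribution of the screening statistic across probes.
#'
#' @param object A `probe_ranking`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.probe_ranking <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue", color = "white") +
    ggplot2::labs(x = paste0(object$method[1], " statistic"), y = "probes") +
    ggplot2::theme_minimal()
}
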