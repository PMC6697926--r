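#' Genomic-region profile of a probe set
#'
#' Characterizes a probe set (typically a model's final predictors)
#' against manifest annotation: the fraction of probes falling in CpG
#' islands, gene bodies and promoters, next to the same fractions over all
#' annotated probes as baseline. A promoter probe is one whose gene-region
#' annotation meets TSS200 or TSS1500; categories overlap, so the
#' fractions need not sum to 1. Probes absent from the annotation are
#' excluded from the denominator and reported.
#'
#' @param probes Character vector of probe ids (de-duplicated internally).
#' @param ann Annotation tibble from [read_probe_annotation()].
#' @return A `region_profile` tibble: one row per category (`Island`,
#'   `Body`, `Promoter`) with `fraction`, `baseline` and counts;
#'   attributes `n_probes` (denominator) and `unannotated_probes`.
#' @export
region_fractions <- function(probes, ann) {
  probes <- unique(as.character(probes))
  if (length(probes) == 0) stop("empty probe set")
  hit <- probes %in% ann$probe_id
  unann <- probes[!hit]
  probes <- probes[hit]
  if (length(probes) == 0) stop("no probe of the set is annotated")

  category_flags <- function(a) {
    tibble::tibble(
      Island = a$island_relation == "Island",
      Body = vapply(a$gene_region, function(r) "Body" %in% r, logical(1)),
      Promoter = vapply(a$gene_region,
                        function(r) any(c("TSS200", "TSS1500") %in% r),
                        logical(1))
    )
  }
  sub <- ann[match(probes, ann$probe_id), , drop = FALSE]
  f_set <- category_flags(sub)
  f_all <- category_flags(ann)
  out <- tibble::tibble(
    category = c("Island", "Body", "Promoter"),
    n = unname(vapply(f_set, sum, integer(1))),
    fraction = unname(vapply(f_set, mean, numeric(1))),
    baseline = unname(vapply(f_all, mean, numeric(1)))
  )
  attr(out, "n_probes") <- length(probes)
  attr(out, "n_baseline") <- nrow(ann)
  attr(out, "unannotated_probes") <- unann
  class(out) <- c("region_profile", class(out))
  out
}

#' Tumor-suppressor-gene overlap of a probe set
#'
#' Fraction of annotated probes with at least one gene symbol on a
#' tumor-suppressor list (TSGene-2.0-style, one symbol per line), plus the
#' matched symbols. A probe matching several listed genes counts once in
#' the fraction but contributes every symbol to the list. Matching is
#' exact and case-sensitive after whitespace trimming.
#'
#' @param probes Character vector of probe ids.
#' @param ann Annotation tibble from [read_probe_annotation()].
#' @param tsg Non-empty character vector of tumor-suppressor gene symbols.
#' @return A list with `fraction`, `n_probes` (denominator), `n_matched`,
#'   and `matched_genes` (sorted unique symbols).
#' @export
tsg_overlap_fraction <- function(probes, ann, tsg) {
  if (length(tsg) == 0) stop("empty tumor-suppressor gene list")
  tsg <- trimws(as.character(tsg))
  probes <- unique(as.character(probes))
  if (length(probes) == 0) stop("empty probe set")
  probes <- probes[probes %in% ann$probe_id]
  if (length(probes) == 0) stop("no probe of the set is annotated")
  sub <- ann[match(probes, ann$probe_id), , drop = FALSE]
  hits <- lapply(sub$gene_symbols, function(g) intersect(trimws(g), tsg))
  matched <- vapply(hits, function(h) length(h) > 0, logical(1))
  list(fraction = mean(matched),
       n_probes = length(probes),
       n_matched = sum(matched),
       matched_genes = sort(unique(unlist(hits))))
}

#' Plot a region profile
#'
#' Model probe-set fractions against the all-array baseline per category.
#'
#' @param object A `region_profile` from [region_fractions()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.region_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object[, c("category", "fraction", "baseline")],
                              cols = c("fraction", "baseline"),
                              names_to = "set", values_to = "value")
  long$set <- ifelse(long$set == "fraction", "probe set", "all probes")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$value,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c("probe set" = "firebrick",
                                          "all probes" = "grey60")) +
    ggplot2::labs(x = NULL, y = "fraction of probes", fill = NULL) +
    ggplot2::theme_minimal()
}
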