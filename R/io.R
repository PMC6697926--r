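#' @useDynLib purityforest, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

MODEL_FORMAT_VERSION <- "purityforest-model/1"

ISLAND_CATEGORIES <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                       "OpenSea")
GENE_REGIONS <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR")
PURITY_SOURCES <- c("ABSOLUTE", "ESTIMATE", "LUMP", "RF_PREDICTED",
                    "SYNTHETIC_TRUTH")

validate_beta_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("beta matrix must be a numeric matrix (probes x samples)")
  }
  if (nrow(m) == 0 || ncol(m) == 0) stop("beta matrix has zero extent")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("beta matrix needs probe ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate probe ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  bad <- which(!is.na(m) & (m < 0 | m > 1))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(m))
    stop(sprintf(
      "beta value out of [0, 1]: probe %s, sample %s, value %.6g (%d offending cells)",
      rownames(m)[i[1]], colnames(m)[i[2]], m[bad[1]], length(bad)))
  }
  invisible(m)
}

#' Read a beta-value matrix
#'
#' Reads a tab-separated matrix of methylation beta values with probes as
#' rows (450K convention). The first column holds probe ids, the header row
#' sample ids; missing values are the token `NA`.
#'
#' @param path Path to a TSV file.
#' @param strict If `TRUE` (default) any value outside `[0, 1]` aborts. If
#'   `FALSE`, values within `1e-9` of the boundaries (floating-point dust
#'   from upstream normalisation) are clamped; anything worse still aborts.
#' @return A numeric matrix, probes x samples, with dimnames.
#' @export
read_beta_matrix <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", na.strings = "NA")
  if (ncol(raw) < 2) stop("beta matrix file needs a probe column and at least one sample: ", path)
  probe_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe ids in ", path, ": ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  body <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad_cell <- which(is.na(vals) & !is.na(body))
  if (length(bad_cell)) {
    i <- arrayInd(bad_cell[1], dim(vals))
    stop(sprintf("non-numeric cell in %s: probe %s, sample %s, value '%s'",
                 path, probe_ids[i[1]], sample_ids[i[2]], body[bad_cell[1]]))
  }
  dimnames(vals) <- list(probe_ids, sample_ids)
  if (!strict) {
    dust <- !is.na(vals) & vals > 1 & vals <= 1 + 1e-9
    vals[dust] <- 1
    dust <- !is.na(vals) & vals < 0 & vals >= -1e-9
    vals[dust] <- 0
  }
  validate_beta_matrix(vals)
  vals
}

#' Write a beta-value matrix
#'
#' Inverse of [read_beta_matrix()]: values round-trip bit-identically
#' (doubles are written with shortest-roundtrip precision) and `NA` cells
#' are preserved.
#'
#' @param m Numeric probes x samples matrix with dimnames, values in
#'   `[0, 1]` or `NA`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(m, path) {
  validate_beta_matrix(m)
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(probe_id = rownames(m)), df)
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

validate_purity_table <- function(p) {
  stopifnot(is.data.frame(p))
  if (!all(c("sample_id", "purity", "source") %in% names(p))) {
    stop("purity table needs columns sample_id, purity, source")
  }
  if (anyDuplicated(p$sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(p$sample_id[duplicated(p$sample_id)]), collapse = ", "))
  }
  bad <- which(!is.na(p$purity) & (p$purity < 0 | p$purity > 1))
  if (length(bad)) {
    stop(sprintf("purity out of [0, 1]: sample %s, value %.6g",
                 p$sample_id[bad[1]], p$purity[bad[1]]))
  }
  invisible(p)
}

new_purity_table <- function(sample_id, purity, source, group = NULL) {
  source <- match.arg(source, PURITY_SOURCES)
  out <- tibble::tibble(sample_id = as.character(sample_id),
                        purity = as.numeric(purity),
                        source = source)
  if (!is.null(group)) out$group <- as.character(group)
  validate_purity_table(out)
  out
}

#' Read a per-sample purity table
#'
#' Reads a TSV with columns `sample_id`, `purity` (in `[0, 1]`), and
#' optionally `group` (entity / subgroup label) and `source`. The label
#' source -- which gold standard or predictor produced the values -- is
#' taken from the `source` column if present, else from the `source`
#' argument.
#'
#' @param path Path to a TSV file.
#' @param source Label source, one of `ABSOLUTE`, `ESTIMATE`, `LUMP`,
#'   `RF_PREDICTED`, `SYNTHETIC_TRUTH`. Required when the file has no
#'   `source` column.
#' @return A tibble with columns `sample_id`, `purity`, `source`, and
#'   `group` when present.
#' @export
read_purity_table <- function(path, source = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "purity") %in% names(df))) {
    stop("purity table ", path, " needs columns sample_id and purity")
  }
  if (!"source" %in% names(df)) {
    if (is.null(source)) stop("no source column in ", path,
                              " and no `source` argument given")
    df$source <- match.arg(source, PURITY_SOURCES)
  } else if (!all(df$source %in% PURITY_SOURCES)) {
    stop("unknown purity source in ", path, ": ",
         paste(setdiff(unique(df$source), PURITY_SOURCES), collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  lead <- intersect(c("sample_id", "purity", "source", "group"), names(df))
  df <- df[, c(lead, setdiff(names(df), lead))]
  validate_purity_table(df)
  df
}

#' Write a per-sample purity table
#' @param p Purity tibble (see [read_purity_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_purity_table <- function(p, path) {
  validate_purity_table(p)
  readr::write_tsv(p, path, na = "NA")
  invisible(path)
}

split_field <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

#' Read a probe annotation table
#'
#' Reads a CSV modeled on the Illumina 450K manifest: columns `probe_id`,
#' `gene_symbols` (semicolon-separated, possibly empty), `gene_region`
#' (semicolon-separated subset of TSS200, TSS1500, 5'UTR, 1stExon, Body,
#' 3'UTR) and `island_relation` (exactly one of Island, N_Shore, S_Shore,
#' N_Shelf, S_Shelf, OpenSea).
#'
#' @param path Path to a CSV file.
#' @return A tibble with list-columns `gene_symbols` and `gene_region` and
#'   a character `island_relation`.
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("probe_id", "gene_symbols", "gene_region", "island_relation")
  if (!all(need %in% names(df))) {
    stop("annotation ", path, " needs columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$probe_id)) {
    stop("duplicate probe ids in annotation: ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  }
  bad <- is.na(df$island_relation) | !(df$island_relation %in% ISLAND_CATEGORIES)
  if (any(bad)) {
    stop("unknown island_relation category: ",
         paste(unique(df$island_relation[bad]), collapse = ", "),
         " (probe ", df$probe_id[which(bad)[1]], ")")
  }
  regions <- split_field(df$gene_region)
  bad_region <- vapply(regions, function(v) any(!v %in% GENE_REGIONS), logical(1))
  if (any(bad_region)) {
    i <- which(bad_region)[1]
    stop("unknown gene_region for probe ", df$probe_id[i], ": ",
         paste(setdiff(regions[[i]], GENE_REGIONS), collapse = ", "))
  }
  tibble::tibble(probe_id = df$probe_id,
                 gene_symbols = split_field(df$gene_symbols),
                 gene_region = regions,
                 island_relation = df$island_relation)
}

#' Read a plain-text probe or gene list
#'
#' One identifier per line (the TSGene-export / LUMP-panel style); blank
#' lines are dropped, surrounding whitespace trimmed.
#'
#' @param path Path to a text file.
#' @return Character vector of identifiers.
#' @export
read_probe_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Save / load a trained purity model
#'
#' The archive is a single file embedding a format-version string, the
#' fitted ensemble, the final probe set, the candidate sweep with its OOB
#' errors, the training-set probe medians used for imputation at
#' prediction, and the full training provenance (config, seed, partition).
#' Loading checks the format version and fails cleanly on a truncated or
#' corrupted file; a reloaded model reproduces the original's predictions
#' bit-identically.
#'
#' @param model A `purity_model` from [train_purity_model()].
#' @param path Archive path.
#' @return `save_purity_model()`: `path`, invisibly.
#'   `load_purity_model()`: the model.
#' @export
save_purity_model <- function(model, path) {
  if (!inherits(model, "purity_model")) stop("`model` is not a purity_model")
  saveRDS(list(format = MODEL_FORMAT_VERSION, model = model), path)
  invisible(path)
}

#' @rdname save_purity_model
#' @export
load_purity_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupted model archive ", path,
                                           ": ", conditionMessage(e)))
  if (!is.list(obj) || is.null(obj$format)) {
    stop("corrupted model archive ", path, ": no format marker")
  }
  if (!identical(obj$format, MODEL_FORMAT_VERSION)) {
    stop("model archive version mismatch: file has '", obj$format,
         "', this build reads '", MODEL_FORMAT_VERSION, "'")
  }
  if (!inherits(obj$model, "purity_model")) {
    stop("corrupted model archive ", path, ": payload is not a purity_model")
  }
  obj$model
}
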