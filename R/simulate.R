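#' Configuration for the synthetic tumor--stroma admixture simulator
#'
#' The simulator emulates the structure a methylation-based purity method
#' is trained on: per-entity tumor methylomes, a shared stromal/immune
#' methylome, linear mixing of the two on the beta scale by each sample's
#' purity, heteroscedastic measurement noise on the logit scale, planted
#' purity-informative probes that become multimodal across the cohort, and
#' two correlated-but-offset gold-standard label sets emulating the
#' systematic difference between an expression-based (ESTIMATE-like) and a
#' copy-number-based (ABSOLUTE-like) purity call.
#'
#' @param n_entities Number of tumor entities (cohort subgroups).
#' @param samples_per_entity Samples simulated per entity.
#' @param n_probes Total CpG probes.
#' @param n_informative Planted purity-informative probes: tumor and stromal
#'   reference betas differ by at least 0.7, so the mixture places beta at
#'   an intermediate level that tracks purity.
#' @param purity_shape List of `c(alpha, beta)` Beta-law parameters, one per
#'   entity, from which sample purities are drawn. The defaults place the
#'   entities at mean purities 0.90, 0.60 and 0.30 -- the span of real
#'   copy-number-based entity means, from near-pure tumors to heavily
#'   infiltrated ones. Entities must differ in typical purity for the
#'   planted probes to be multimodal across the cohort; with one shared
#'   law the cohort purity is unimodal and so are the planted probes.
#' @param noise_sd Measurement noise SD on the logit-beta scale.
#' @param label_offset_estimate Mean logit-scale shift added to the
#'   ESTIMATE-like labels (positive: ESTIMATE reads systematically higher).
#' @param label_noise_sd Logit-scale SD of the label noise around the true
#'   purity, for both label sets.
#' @param missing_rate Fraction of beta cells masked to `NA`.
#' @param n_entity_probes Non-informative probes receiving entity-specific
#'   tumor-methylome perturbations.
#' @param entity_effect_sd Logit-scale SD of those perturbations.
#' @param lump_panel_size Size of the emulated immune-hypomethylation (LUMP)
#'   probe panel, drawn from tumor-high/stroma-low informative probes.
#' @param seed Master seed; all stages draw from seeds derived from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_entities = 3,
                              samples_per_entity = 100,
                              n_probes = 20000,
                              n_informative = 600,
                              purity_shape = list(c(45, 5), c(30, 20), c(15, 35)),
                              noise_sd = 0.3,
                              label_offset_estimate = 0.25,
                              label_noise_sd = 0.2,
                              missing_rate = 0,
                              n_entity_probes = 500,
                              entity_effect_sd = 1,
                              lump_panel_size = 44,
                              seed = 1) {
  cfg <- list(n_entities = n_entities, samples_per_entity = samples_per_entity,
              n_probes = n_probes, n_informative = n_informative,
              purity_shape = purity_shape, noise_sd = noise_sd,
              label_offset_estimate = label_offset_estimate,
              label_noise_sd = label_noise_sd, missing_rate = missing_rate,
              n_entity_probes = n_entity_probes,
              entity_effect_sd = entity_effect_sd,
              lump_panel_size = lump_panel_size, seed = seed)
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  counts <- c("n_entities", "samples_per_entity", "n_probes")
  for (k in counts) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != floor(v)) {
      stop("config ", k, " must be a positive integer, got ", format(v))
    }
  }
  if (cfg$n_informative < 0 || cfg$n_informative > cfg$n_probes) {
    stop("n_informative must lie in [0, n_probes]")
  }
  if (cfg$n_entity_probes < 0 ||
      cfg$n_entity_probes > cfg$n_probes - cfg$n_informative) {
    stop("n_entity_probes must fit among the non-informative probes")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (cfg$noise_sd < 0 || cfg$label_noise_sd < 0) stop("noise SDs must be >= 0")
  if (length(cfg$purity_shape) != cfg$n_entities) {
    stop("purity_shape needs one c(alpha, beta) pair per entity")
  }
  ok <- vapply(cfg$purity_shape,
               function(v) is.numeric(v) && length(v) == 2 && all(v > 0),
               logical(1))
  if (!all(ok)) stop("each purity_shape entry must be c(alpha, beta), both > 0")
  if (cfg$lump_panel_size < 0 || cfg$lump_panel_size > cfg$n_informative) {
    stop("lump_panel_size must lie in [0, n_informative]")
  }
  if (!is.numeric(cfg$seed) || cfg$seed != floor(cfg$seed)) {
    stop("seed must be an integer")
  }
  invisible(cfg)
}

# One derived seed per simulation stage so stages are independently
# reproducible; all flow from the master seed.
stage_seeds <- function(seed, n = 6) {
  withr::with_seed(seed, sample.int(.Machine$integer.max, n))
}

clip01 <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

logit_jitter <- function(p, shift, sd) {
  stats::plogis(stats::qlogis(clip01(p)) + shift + stats::rnorm(length(p), 0, sd))
}

#' Draw the tumor and stromal reference methylomes
#'
#' Informative probes get opposed tumor/stroma reference betas (one drawn
#' from a high law on `[0.85, 0.95]`, the other from a low law on
#' `[0.05, 0.15]`, direction random per probe), so the two compartments
#' disagree by at least 0.7. Non-informative probes share one reference
#' value drawn from a U-shaped Beta(0.5, 0.5), the typical bimodal
#' across-probe landscape of a 450K array; a configurable subset of them
#' additionally receives entity-specific logit-scale perturbations of the
#' tumor methylome.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `tumor` (probes x entities matrix), `stroma`
#'   (vector), `informative_probes`, `entity_probes`, `lump_panel`,
#'   and `probe_ids`.
#' @export
draw_reference_profiles <- function(cfg) {
  validate_simulation_config(cfg)
  seeds <- stage_seeds(cfg$seed)
  probe_ids <- sprintf("cg%06d", seq_len(cfg$n_probes))
  entities <- sprintf("E%02d", seq_len(cfg$n_entities))

  withr::with_seed(seeds[1], {
    base <- stats::rbeta(cfg$n_probes, 0.5, 0.5)
    informative <- sort(sample.int(cfg$n_probes, cfg$n_informative))
    rest <- setdiff(seq_len(cfg$n_probes), informative)
    entity_idx <- sort(sample(rest, cfg$n_entity_probes))

    stroma <- base
    tumor_base <- base
    if (cfg$n_informative > 0) {
      hi <- 0.85 + 0.10 * stats::rbeta(cfg$n_informative, 2, 2)
      lo <- 0.05 + 0.10 * stats::rbeta(cfg$n_informative, 2, 2)
      tumor_high <- stats::runif(cfg$n_informative) < 0.5
      tumor_base[informative] <- ifelse(tumor_high, hi, lo)
      stroma[informative] <- ifelse(tumor_high, lo, hi)
    } else {
      tumor_high <- logical(0)
    }

    tumor <- matrix(tumor_base, nrow = cfg$n_probes, ncol = cfg$n_entities,
                    dimnames = list(probe_ids, entities))
    if (cfg$n_entity_probes > 0 && cfg$entity_effect_sd > 0) {
      shift <- matrix(stats::rnorm(cfg$n_entity_probes * cfg$n_entities,
                                   0, cfg$entity_effect_sd),
                      nrow = cfg$n_entity_probes)
      tumor[entity_idx, ] <- stats::plogis(
        stats::qlogis(clip01(tumor[entity_idx, , drop = FALSE])) + shift)
    }

    lump_panel <- character(0)
    if (cfg$lump_panel_size > 0) {
      # immune/stromal compartment unmethylated, tumor methylated
      candidates <- informative[tumor_high]
      if (length(candidates) < cfg$lump_panel_size) {
        stop("not enough tumor-high informative probes for the LUMP panel")
      }
      lump_panel <- probe_ids[sort(sample(candidates, cfg$lump_panel_size))]
    }
  })

  names(stroma) <- probe_ids
  list(tumor = tumor, stroma = stroma,
       informative_probes = probe_ids[informative],
       entity_probes = probe_ids[entity_idx],
       lump_panel = lump_panel,
       probe_ids = probe_ids)
}

#' Simulate a tumor--stroma admixture cohort
#'
#' Draws per-sample purities from each entity's Beta law, mixes the entity's
#' tumor methylome with the shared stromal methylome linearly on the beta
#' scale, and adds logit-scale noise:
#' `beta = logistic(logit(p * t + (1 - p) * s) + eps)`, with values clipped
#' to `[1e-6, 1 - 1e-6]` before the logit. With `noise_sd = 0` the betas
#' are the exact convex combination. Two gold-standard label sets are
#' derived from the true purity with independent logit-scale noise; the
#' ESTIMATE-like set additionally gets a positive mean offset, reproducing
#' the systematic ESTIMATE-above-ABSOLUTE difference.
#'
#' @param cfg A [simulation_config()].
#' @return A `synthetic_cohort` list: `betas` (probes x samples matrix),
#'   `truth`, `labels_absolute_like`, `labels_estimate_like` (purity
#'   tibbles with a `group` column), `entity` (named vector),
#'   `informative_probes`, `entity_probes`, `lump_panel`, `profiles`, and
#'   the `config`.
#' @export
simulate_cohort <- function(cfg) {
  validate_simulation_config(cfg)
  seeds <- stage_seeds(cfg$seed)
  prof <- draw_reference_profiles(cfg)

  n_samples <- cfg$n_entities * cfg$samples_per_entity
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  entity <- rep(colnames(prof$tumor), each = cfg$samples_per_entity)
  names(entity) <- sample_ids

  purity <- withr::with_seed(seeds[2], {
    unlist(lapply(seq_len(cfg$n_entities), function(e) {
      sh <- cfg$purity_shape[[e]]
      stats::rbeta(cfg$samples_per_entity, sh[1], sh[2])
    }))
  })
  names(purity) <- sample_ids

  # mixing: columns are samples; entity selects the tumor profile
  mix <- sweep(prof$tumor[, entity, drop = FALSE], 2, purity, `*`) +
    outer(prof$stroma, 1 - purity)
  dimnames(mix) <- list(prof$probe_ids, sample_ids)

  betas <- mix
  if (cfg$noise_sd > 0) {
    betas <- withr::with_seed(seeds[3], {
      eps <- matrix(stats::rnorm(length(mix), 0, cfg$noise_sd), nrow = nrow(mix))
      stats::plogis(stats::qlogis(clip01(mix)) + eps)
    })
    dimnames(betas) <- dimnames(mix)
  }
  if (cfg$missing_rate > 0) {
    betas <- withr::with_seed(seeds[4], {
      mask <- stats::runif(length(betas)) < cfg$missing_rate
      betas[mask] <- NA_real_
      betas
    })
  }

  labels <- withr::with_seed(seeds[5], {
    list(absolute = logit_jitter(purity, 0, cfg$label_noise_sd),
         estimate = logit_jitter(purity, cfg$label_offset_estimate,
                                 cfg$label_noise_sd))
  })

  out <- list(
    betas = betas,
    truth = new_purity_table(sample_ids, purity, "SYNTHETIC_TRUTH", entity),
    labels_absolute_like = new_purity_table(sample_ids, labels$absolute,
                                            "ABSOLUTE", entity),
    labels_estimate_like = new_purity_table(sample_ids, labels$estimate,
                                            "ESTIMATE", entity),
    entity = entity,
    informative_probes = prof$informative_probes,
    entity_probes = prof$entity_probes,
    lump_panel = prof$lump_panel,
    profiles = prof,
    config = cfg
  )
  class(out) <- "synthetic_cohort"
  out
}

#' Generate a synthetic probe annotation table
#'
#' Builds a manifest-style annotation for a probe set: per probe zero to
#' two synthetic gene symbols, a gene-region subset and one CpG-island
#' category, with a designated fraction of genes flagged as tumor
#' suppressors. Purely synthetic identifiers -- a stand-in for a real
#' manifest in tests and fixtures.
#'
#' @param probe_ids Probes to annotate.
#' @param n_genes Size of the synthetic gene pool.
#' @param tsg_fraction Fraction of the gene pool designated tumor
#'   suppressors.
#' @param seed Seed.
#' @return A list with `annotation` (tibble as from
#'   [read_probe_annotation()]) and `tsg` (character vector of the
#'   designated tumor-suppressor symbols).
#' @export
simulate_probe_annotation <- function(probe_ids, n_genes = 400,
                                      tsg_fraction = 0.1, seed = 1) {
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  withr::with_seed(seed, {
    tsg <- sort(sample(genes, max(1, round(tsg_fraction * n_genes))))
    n_gene_hits <- sample(0:2, length(probe_ids), replace = TRUE,
                          prob = c(0.25, 0.6, 0.15))
    gene_symbols <- lapply(n_gene_hits, function(k) {
      if (k == 0) character(0) else sort(sample(genes, k))
    })
    gene_region <- lapply(n_gene_hits, function(k) {
      if (k == 0) return(character(0))
      sort(sample(GENE_REGIONS, sample(1:2, 1)))
    })
    island_relation <- sample(ISLAND_CATEGORIES, length(probe_ids),
                              replace = TRUE,
                              prob = c(0.31, 0.13, 0.12, 0.05, 0.05, 0.34))
  })
  list(annotation = tibble::tibble(probe_id = probe_ids,
                                   gene_symbols = gene_symbols,
                                   gene_region = gene_region,
                                   island_relation = island_relation),
       tsg = tsg)
}

write_probe_annotation <- function(ann, path) {
  df <- tibble::tibble(
    probe_id = ann$probe_id,
    gene_symbols = vapply(ann$gene_symbols, paste, "", collapse = ";"),
    gene_region = vapply(ann$gene_region, paste, "", collapse = ";"),
    island_relation = ann$island_relation
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' Write a complete synthetic fixture suite
#'
#' Simulates a cohort and writes every artifact the pipeline consumes to
#' one directory: the beta matrix, the three purity tables (synthetic
#' truth and the two emulated gold standards), a synthetic manifest-style
#' annotation, a synthetic tumor-suppressor gene list, and the emulated
#' LUMP probe panel. Deterministic: repeated calls with the same config
#' produce byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param cfg A [simulation_config()].
#' @return Named character vector of the files written, invisibly; the
#'   simulated cohort is attached as attribute `cohort`.
#' @export
make_fixture_suite <- function(out_dir, cfg = simulation_config()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory ", out_dir)
  }
  if (file.access(out_dir, mode = 2) != 0) stop("directory not writable: ", out_dir)
  co <- simulate_cohort(cfg)
  ann <- simulate_probe_annotation(rownames(co$betas), seed = cfg$seed)
  paths <- c(
    betas = file.path(out_dir, "betas.tsv"),
    truth = file.path(out_dir, "purity_truth.tsv"),
    labels_absolute = file.path(out_dir, "purity_absolute_like.tsv"),
    labels_estimate = file.path(out_dir, "purity_estimate_like.tsv"),
    annotation = file.path(out_dir, "annotation.csv"),
    tsg = file.path(out_dir, "tsg_list.txt"),
    lump_panel = file.path(out_dir, "lump_panel.txt")
  )
  write_beta_matrix(co$betas, paths["betas"])
  write_purity_table(co$truth, paths["truth"])
  write_purity_table(co$labels_absolute_like, paths["labels_absolute"])
  write_purity_table(co$labels_estimate_like, paths["labels_estimate"])
  write_probe_annotation(ann$annotation, paths["annotation"])
  writeLines(ann$tsg, paths["tsg"])
  writeLines(co$lump_panel, paths["lump_panel"])
  attr(paths, "cohort") <- co
  invisible(paths)
}
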