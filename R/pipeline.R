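#' Configuration for a full analysis run
#'
#' Bundles every tunable of the end-to-end pipeline. A seed is mandatory:
#' all randomness in a run derives from it, with an independent stream per
#' stage (forked by stage name) so that adding a stage does not perturb
#' the draws of the others.
#'
#' @param design A [cohort_design()] to simulate from, or `NULL` when
#'   reading data from files.
#' @param matrix_path,annotation_path,ortholog_path Input files, used when
#'   `design` is `NULL`. For cross-species runs `matrix_path` and
#'   `annotation_path` are length-2 named vectors (`human`, `mouse`).
#' @param signature_size Genes per signature direction (default 150).
#' @param fdr FDR level of the tissue filter (default 0.05).
#' @param permutations Permutations per significance test (default 1000).
#' @param seed Integer seed (mandatory).
#' @param per_sample Score references per sample (default) or per subset
#'   mean.
#' @param linkage Dendrogram linkage, `"average"` or `"complete"`.
#' @param ortholog_policy Signature translation policy, see
#'   [map_signature()].
#' @param center Median-center samples before analysis (default `TRUE`).
#' @param query_subset Within-species query subset; default: the first
#'   `cd141_like` subset of a simulated design, else the alphabetically
#'   first subset.
#' @param queries Named list of human subset-label vectors to pool into
#'   cross-species query signatures; default: one pooled query per
#'   lineage shared between the two species of a simulated design.
#' @return An `AnalysisConfig` object.
#' @export
analysis_config <- function(design = NULL,
                            matrix_path = NULL, annotation_path = NULL,
                            ortholog_path = NULL,
                            signature_size = 150, fdr = 0.05,
                            permutations = 1000, seed,
                            per_sample = TRUE,
                            linkage = c("average", "complete"),
                            ortholog_policy = c("one_to_one_only", "expand_all"),
                            center = TRUE,
                            query_subset = NULL, queries = NULL) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    stop("`seed` is mandatory and must be an integer")
  }
  if (is.null(design) && is.null(matrix_path)) {
    stop("provide either a `design` to simulate or input file paths")
  }
  if (!is.null(matrix_path)) {
    missing_files <- matrix_path[!file.exists(matrix_path)]
    if (length(missing_files)) {
      stop("matrix file(s) not found: ", paste(missing_files, collapse = ", "))
    }
  }
  structure(list(design = design,
                 matrix_path = matrix_path,
                 annotation_path = annotation_path,
                 ortholog_path = ortholog_path,
                 signature_size = signature_size,
                 fdr = fdr,
                 permutations = as.integer(permutations),
                 seed = as.integer(seed),
                 per_sample = isTRUE(per_sample),
                 linkage = match.arg(linkage),
                 ortholog_policy = match.arg(ortholog_policy),
                 center = isTRUE(center),
                 query_subset = query_subset,
                 queries = queries),
            class = "AnalysisConfig")
}

#' Read a flat key-value (YAML) configuration file
#'
#' Scalar keys are passed straight to [analysis_config()]. A design
#' cannot be expressed in the flat file; file-based inputs only.
#'
#' @param path YAML file path.
#' @return An `AnalysisConfig`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(analysis_config, cfg)
}

# fork a deterministic per-stage seed from the run seed and the stage name
stage_seed <- function(seed, stage) {
  h <- 0
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% 1000003
  as.integer((as.numeric(seed) + h * 877) %% 2147483647)
}

# small polynomial checksum over file bytes; for the audit log only
file_checksum <- function(path) {
  bytes <- as.integer(readBin(path, "raw", file.size(path)))
  h <- 0
  for (b in bytes) h <- (h * 257 + b) %% 4294967291
  sprintf("%010.0f", h)
}

load_or_simulate <- function(cfg) {
  if (!is.null(cfg$design)) {
    design <- cfg$design
    design$seed <- stage_seed(cfg$seed, "simulate")
    generate_cohort(design)
  } else {
    nm <- names(cfg$matrix_path)
    if (is.null(nm)) nm <- rep("human", length(cfg$matrix_path))
    expression <- stats::setNames(lapply(seq_along(cfg$matrix_path), function(i) {
      read_expression(cfg$matrix_path[[i]], cfg$annotation_path[[i]])
    }), nm)
    orth <- if (!is.null(cfg$ortholog_path)) read_orthologs(cfg$ortholog_path)
    list(expression = expression, orthologs = orth, truth = NULL)
  }
}

default_query_subset <- function(cfg, m) {
  if (!is.null(cfg$query_subset)) return(cfg$query_subset)
  if (!is.null(cfg$design)) {
    sub <- cfg$design$subsets
    cand <- sub$subset[sub$lineage == "cd141_like" &
                         sub$subset %in% m$samples$subset]
    if (length(cand)) return(cand[[1L]])
  }
  sort(unique(m$samples$subset), method = "radix")[[1L]]
}

default_queries <- function(cfg, human, mouse) {
  if (!is.null(cfg$queries)) return(cfg$queries)
  if (is.null(cfg$design)) {
    stop("cross-species `queries` must be given when not simulating")
  }
  sub <- cfg$design$subsets
  shared <- intersect(sub$lineage[sub$species == "human"],
                      sub$lineage[sub$species == "mouse"])
  shared <- setdiff(shared, "none")
  stats::setNames(lapply(shared, function(lin) {
    unique(sub$subset[sub$species == "human" & sub$lineage == lin])
  }), paste0(shared, "_query"))
}

pipe_log <- function(lines, stage, msg) c(lines, sprintf("[%s] %s", stage, msg))

#' Within-species analysis: dendrogram and connectivity table
#'
#' Runs the single-species arm of the pipeline on a two-tissue cohort:
#' simulate (or load), median-center, identify and remove tissue-specific
#' genes, derive a per-subset signature for every subset, cluster
#' subset-by-tissue mean profiles, and score the query subset's signature
#' against all reference profiles. Every intermediate artifact is written
#' to `out_dir` in a re-readable plain-text format, plus an audit log
#' with the configuration echo and input checksums. Identical
#' configuration and seed reproduce byte-identical outputs.
#'
#' @param cfg An [analysis_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list: `matrix` (filtered, centered
#'   `ExpressionMatrix`), `tissue_genes`, `signatures` (named list),
#'   `tree` (`hclust`), `enrichment` (`EnrichmentResult`), `truth`.
#' @export
run_within_species <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "AnalysisConfig"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log <- character(0)

  data <- load_or_simulate(cfg)
  m <- data$expression[[1L]]
  if (!is.null(data$expression[["human"]])) m <- data$expression[["human"]]
  log <- pipe_log(log, "load", sprintf("%d genes x %d samples", nrow(m$values),
                                       ncol(m$values)))
  tissues <- sort(unique(m$samples$tissue), method = "radix")
  if (length(tissues) != 2L) {
    stop("within-species run needs exactly 2 tissues, found: ",
         paste(tissues, collapse = ", "))
  }
  if (cfg$center) m <- center_samples(m)

  tg <- tissue_specific_genes(m, tissues[[1L]], tissues[[2L]], alpha = cfg$fdr)
  if (length(tg)) {
    write_gmt(stats::setNames(list(structure(tg, description = paste(tissues, collapse = "_vs_"))),
                              "tissue_specific"),
              file.path(out_dir, "tissue_genes.gmt"))
  } else {
    writeLines(character(0), file.path(out_dir, "tissue_genes.gmt"))
  }
  log <- pipe_log(log, "tissue_filter", sprintf("%d tissue-specific genes", length(tg)))

  filtered <- remove_genes(m, tg)
  write_expression(filtered, file.path(out_dir, "filtered_matrix.tsv"),
                   file.path(out_dir, "filtered_annotations.tsv"))

  subsets <- sort(unique(filtered$samples$subset), method = "radix")
  sigs <- stats::setNames(lapply(subsets, function(s) {
    derive_signature(filtered, s, size = cfg$signature_size)
  }), subsets)
  write_signature(sigs, file.path(out_dir, "signatures.gmt"))
  log <- pipe_log(log, "signatures", sprintf("%d subset signatures of %d+%d genes",
                                             length(sigs), cfg$signature_size,
                                             cfg$signature_size))

  means <- subset_mean_profile(filtered, c("subset", "tissue"))
  tree <- hcluster(correlation_distance(means), linkage = cfg$linkage)
  write_newick(tree, file.path(out_dir, "dendrogram.nwk"))
  log <- pipe_log(log, "cluster", sprintf("%d leaves, %s linkage",
                                          length(tree$labels), cfg$linkage))

  query <- default_query_subset(cfg, filtered)
  enr <- enrichment_table(sigs[[query]], filtered, per_sample = cfg$per_sample,
                          B = cfg$permutations,
                          seed = stage_seed(cfg$seed, "enrich"))
  utils::write.table(enr$scores, file.path(out_dir, "enrichment_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(enr$by_subset, file.path(out_dir, "enrichment_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- pipe_log(log, "enrich", sprintf("query '%s', B = %d", query,
                                         cfg$permutations))

  log <- pipe_log(log, "config", sprintf(
    "seed=%d size=%d fdr=%g B=%d linkage=%s center=%s per_sample=%s",
    cfg$seed, cfg$signature_size, cfg$fdr, cfg$permutations, cfg$linkage,
    cfg$center, cfg$per_sample))
  for (f in c("tissue_genes.gmt", "filtered_matrix.tsv", "signatures.gmt",
              "dendrogram.nwk", "enrichment_scores.tsv")) {
    log <- pipe_log(log, "checksum",
                    sprintf("%s %s", f, file_checksum(file.path(out_dir, f))))
  }
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(list(matrix = filtered, tissue_genes = tg, signatures = sigs,
                 tree = tree, enrichment = enr, truth = data$truth))
}

#' Cross-species analysis: lineage signatures scored on mouse subsets
#'
#' Runs the two-species arm of the pipeline: simulate (or load) both
#' cohorts, median-center, remove human tissue-specific genes, build one
#' pooled signature per query (by default one per lineage shared between
#' the species), translate each signature into mouse gene space through
#' the ortholog table, and score it against every mouse reference
#' profile with permutation significance.
#'
#' @inheritParams run_within_species
#' @return Invisibly, a list: `signatures` (pooled human signatures),
#'   `mapped` (their mouse translations), `enrichment` (named list of
#'   `EnrichmentResult`, one per query), `orthologs`, `truth`.
#' @export
run_cross_species <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "AnalysisConfig"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log <- character(0)

  data <- load_or_simulate(cfg)
  if (!all(c("human", "mouse") %in% names(data$expression))) {
    stop("cross-species run needs 'human' and 'mouse' expression matrices")
  }
  if (is.null(data$orthologs)) stop("cross-species run needs an ortholog table")
  human <- data$expression[["human"]]
  mouse <- data$expression[["mouse"]]
  if (cfg$center) {
    human <- center_samples(human)
    mouse <- center_samples(mouse)
  }
  log <- pipe_log(log, "load", sprintf("human %d samples, mouse %d samples",
                                       ncol(human$values), ncol(mouse$values)))

  tissues <- sort(unique(human$samples$tissue), method = "radix")
  tg <- tissue_specific_genes(human, tissues[[1L]], tissues[[2L]], alpha = cfg$fdr)
  filtered <- remove_genes(human, tg)
  log <- pipe_log(log, "tissue_filter", sprintf("%d tissue-specific genes removed",
                                                length(tg)))

  queries <- default_queries(cfg, human, mouse)
  sigs <- stats::setNames(lapply(names(queries), function(q) {
    pool_signature(filtered, queries[[q]], size = cfg$signature_size, name = q)
  }), names(queries))
  write_signature(sigs, file.path(out_dir, "human_signatures.gmt"))

  mapped <- lapply(sigs, function(s) {
    map_signature(s, data$orthologs, policy = cfg$ortholog_policy)
  })
  for (q in names(mapped)) {
    log <- pipe_log(log, "map", sprintf(
      "%s: retention up %.2f down %.2f", q,
      attr(mapped[[q]], "retention")[["up"]],
      attr(mapped[[q]], "retention")[["down"]]))
  }
  write_signature(mapped, file.path(out_dir, "mapped_signatures.gmt"))

  enr <- stats::setNames(lapply(names(mapped), function(q) {
    enrichment_table(mapped[[q]], mouse, per_sample = cfg$per_sample,
                     B = cfg$permutations,
                     seed = stage_seed(cfg$seed, paste0("enrich_", q)))
  }), names(mapped))
  scores <- do.call(rbind, lapply(enr, `[[`, "scores"))
  summary_ <- do.call(rbind, lapply(enr, `[[`, "by_subset"))
  rownames(scores) <- rownames(summary_) <- NULL
  utils::write.table(scores, file.path(out_dir, "cross_species_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary_, file.path(out_dir, "cross_species_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- pipe_log(log, "enrich", sprintf("%d queries x %d mouse profiles, B = %d",
                                         length(enr), ncol(mouse$values),
                                         cfg$permutations))

  log <- pipe_log(log, "config", sprintf(
    "seed=%d size=%d fdr=%g B=%d policy=%s center=%s per_sample=%s",
    cfg$seed, cfg$signature_size, cfg$fdr, cfg$permutations,
    cfg$ortholog_policy, cfg$center, cfg$per_sample))
  for (f in c("human_signatures.gmt", "mapped_signatures.gmt",
              "cross_species_scores.tsv", "cross_species_summary.tsv")) {
    log <- pipe_log(log, "checksum",
                    sprintf("%s %s", f, file_checksum(file.path(out_dir, f))))
  }
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(list(signatures = sigs, mapped = mapped, enrichment = enr,
                 orthologs = data$orthologs, truth = data$truth))
}
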