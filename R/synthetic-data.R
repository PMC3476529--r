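#' Specify a synthetic two-species cohort
#'
#' A cohort design fixes everything the generator needs: which subsets are
#' profiled per species and tissue, how many replicates each cell of the
#' design has, how many genes carry lineage or tissue signal, and the
#' effect/noise magnitudes (all in log2 units). The generative model is
#' additive Gaussian on the log2 scale, the convention for normalized
#' microarray intensities:
#'
#' \deqn{x = baseline(g) + lineage\_effect \cdot [g \in markers(lineage(s))] +
#'   tissue\_effect \cdot [g \in genes(tissue(s))] + donor + noise}
#'
#' with per-gene baselines Uniform(4, 12), a per-donor scalar offset shared
#' by all genes of that donor's samples (the simplest confounder array
#' normalization and clustering must tolerate), and iid Gaussian noise.
#' Marker genes of a lineage present in both species are linked through
#' 1:1 orthologs, which is the planted homology that cross-species
#' connectivity scoring is expected to recover.
#'
#' @param subsets Data frame with columns `species`, `subset`, `lineage`
#'   (one of `"cd141_like"`, `"cd1c_like"`, `"monocyte_like"`,
#'   `"pdc_like"`, `"none"`), `tissue`, `replicates`. One row per
#'   subset-tissue cell.
#' @param n_genes Genes per species.
#' @param n_marker_genes_per_lineage Planted marker genes per lineage;
#'   marker sets of distinct lineages are disjoint.
#' @param n_tissue_genes_per_tissue Planted tissue-specific genes per
#'   tissue; disjoint from markers and from other tissues' genes.
#' @param lineage_effect,tissue_effect,donor_sd,noise_sd Effect sizes and
#'   noise standard deviations, log2 units, all >= 0.
#' @param ortholog_fraction Proportion of genes given a 1:1 cross-species
#'   ortholog.
#' @param one_to_many_rate Proportion of orthologous human genes that
#'   additionally receive a second mouse partner (exercises the orthology
#'   policy; default 0).
#' @param seed Integer seed; generation is fully deterministic given the
#'   design.
#' @return A `CohortDesign` object.
#' @export
cohort_design <- function(subsets,
                          n_genes = 2000,
                          n_marker_genes_per_lineage = 100,
                          n_tissue_genes_per_tissue = 150,
                          lineage_effect = 2,
                          tissue_effect = 1,
                          donor_sd = 0.25,
                          noise_sd = 0.5,
                          ortholog_fraction = 0.9,
                          one_to_many_rate = 0,
                          seed = 1L) {
  subsets <- as.data.frame(subsets, stringsAsFactors = FALSE)
  need <- c("species", "subset", "lineage", "tissue", "replicates")
  if (!all(need %in% names(subsets))) {
    stop("`subsets` needs columns: ", paste(need, collapse = ", "))
  }
  lin_ok <- c("cd141_like", "cd1c_like", "monocyte_like", "pdc_like", "none")
  if (!all(subsets$lineage %in% lin_ok)) {
    stop("lineage must be one of: ", paste(lin_ok, collapse = ", "))
  }
  if (any(subsets$replicates < 2L)) {
    stop("every subset-tissue cell needs >= 2 replicates")
  }
  if (any(c(lineage_effect, tissue_effect, donor_sd, noise_sd) < 0)) {
    stop("effect sizes and standard deviations must be >= 0")
  }
  if (ortholog_fraction < 0 || ortholog_fraction > 1) {
    stop("ortholog_fraction must lie in [0, 1]")
  }
  lineages <- setdiff(unique(subsets$lineage), "none")
  for (sp in unique(subsets$species)) {
    n_tis <- length(unique(subsets$tissue[subsets$species == sp]))
    used <- length(lineages) * n_marker_genes_per_lineage +
      n_tis * n_tissue_genes_per_tissue
    if (used > n_genes) {
      stop(sprintf("species '%s': %d marker + tissue genes exceed n_genes = %d",
                   sp, used, n_genes))
    }
  }
  structure(list(subsets = subsets,
                 n_genes = as.integer(n_genes),
                 n_marker_genes_per_lineage = as.integer(n_marker_genes_per_lineage),
                 n_tissue_genes_per_tissue = as.integer(n_tissue_genes_per_tissue),
                 lineage_effect = lineage_effect,
                 tissue_effect = tissue_effect,
                 donor_sd = donor_sd,
                 noise_sd = noise_sd,
                 ortholog_fraction = ortholog_fraction,
                 one_to_many_rate = one_to_many_rate,
                 seed = as.integer(seed)),
            class = "CohortDesign")
}

#' Default two-species cohort design
#'
#' Emulates the study design the package targets: human monocyte and DC
#' subsets profiled from six blood donors and four skin donors
#' (CD141+/CD141hi DC, CD1c+ DC and CD14+ monocyte/DC in both tissues;
#' CD16+ monocytes and pDC in blood only), and mouse subsets profiled in
#' four experimental sets each (CD103+ DC and CD11b+ DC in lung and liver,
#' CD8+ and CD4+ DC in spleen, blood monocytes). Lineage assignments plant
#' the homology the analysis should find: CD141/CD103/CD8 form the
#' cross-presenting lineage, CD1c/CD11b/CD4 the cd1c lineage, CD14/CD16
#' and mouse monocytes the monocyte lineage; pDC have no mouse
#' counterpart here.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [cohort_design()].
#' @return A `CohortDesign`.
#' @export
default_cohort_design <- function(seed = 1L, ...) {
  subsets <- rbind(
    data.frame(species = "human",
               subset = c("CD141_DC", "CD1c_DC", "CD14_mono", "CD16_mono", "pDC"),
               lineage = c("cd141_like", "cd1c_like", "monocyte_like",
                           "monocyte_like", "pdc_like"),
               tissue = "blood", replicates = 6L, stringsAsFactors = FALSE),
    data.frame(species = "human",
               subset = c("CD141_DC", "CD1c_DC", "CD14_mono"),
               lineage = c("cd141_like", "cd1c_like", "monocyte_like"),
               tissue = "skin", replicates = 4L, stringsAsFactors = FALSE),
    data.frame(species = "mouse",
               subset = c("CD103_DC", "CD103_DC", "CD11b_DC", "CD11b_DC",
                          "CD8_DC", "CD4_DC", "monocyte"),
               lineage = c("cd141_like", "cd141_like", "cd1c_like", "cd1c_like",
                           "cd141_like", "cd1c_like", "monocyte_like"),
               tissue = c("lung", "liver", "lung", "liver",
                          "spleen", "spleen", "blood"),
               replicates = 4L, stringsAsFactors = FALSE))
  cohort_design(subsets, seed = seed, ...)
}

#' Default human-only design
#'
#' The human half of [default_cohort_design()], for within-species
#' analyses (tissue filtering, signatures, clustering).
#'
#' @inheritParams default_cohort_design
#' @return A `CohortDesign`.
#' @export
human_cohort_design <- function(seed = 1L, ...) {
  d <- default_cohort_design(seed = seed, ...)
  d$subsets <- d$subsets[d$subsets$species == "human", , drop = FALSE]
  rownames(d$subsets) <- NULL
  d
}

gene_prefix <- c(human = "HGENE", mouse = "MGENE")

species_gene_ids <- function(species, n) {
  pre <- gene_prefix[[species]]
  if (is.null(pre)) pre <- toupper(substr(species, 1, 1))
  sprintf("%s_%05d", pre, seq_len(n))
}

#' Generate a synthetic cohort
#'
#' Draws expression matrices for every species in the design, the ortholog
#' table linking them, and the ground truth (planted marker and tissue
#' genes, homologous subset pairs). Deterministic given the design,
#' including its seed.
#'
#' @param design A [cohort_design()].
#' @return A list with elements `expression` (named list of
#'   `ExpressionMatrix`, one per species), `orthologs` (an
#'   [ortholog_table()]; `NULL` for single-species designs), and `truth`
#'   (a `SyntheticTruth` object: `marker_genes` and `tissue_genes` maps
#'   per species, the ortholog table, and the homologous subset pairs
#'   derived from shared lineage labels).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "CohortDesign"))
  set.seed(design$seed)
  subsets <- design$subsets
  species <- unique(subsets$species)
  lineages <- setdiff(unique(subsets$lineage), "none")
  nm <- design$n_marker_genes_per_lineage
  nt <- design$n_tissue_genes_per_tissue
  ng <- design$n_genes

  # marker indices are shared across species so that 1:1 orthologs (paired
  # by index) carry the planted homology
  marker_idx <- stats::setNames(
    lapply(seq_along(lineages), function(i) ((i - 1L) * nm + 1L):(i * nm)),
    lineages)
  n_marker_total <- length(lineages) * nm

  expression <- list()
  marker_genes <- list()
  tissue_genes <- list()

  for (sp in species) {
    sub_sp <- subsets[subsets$species == sp, , drop = FALSE]
    tissues <- unique(sub_sp$tissue)
    ids <- species_gene_ids(sp, ng)
    tg_idx <- stats::setNames(
      lapply(seq_along(tissues), function(i) {
        n_marker_total + ((i - 1L) * nt + 1L):(i * nt)
      }), tissues)
    baseline <- stats::runif(ng, 4, 12)
    # one offset per donor, shared by all of that donor's samples
    donor_offsets <- list()
    for (ti in tissues) {
      ndon <- max(sub_sp$replicates[sub_sp$tissue == ti])
      donor_offsets[[ti]] <- stats::rnorm(ndon, 0, design$donor_sd)
    }
    cols <- list()
    ann <- list()
    for (r in seq_len(nrow(sub_sp))) {
      lin <- sub_sp$lineage[r]
      ti <- sub_sp$tissue[r]
      for (d in seq_len(sub_sp$replicates[r])) {
        v <- baseline + stats::rnorm(ng, 0, design$noise_sd) +
          donor_offsets[[ti]][d]
        if (lin != "none") {
          v[marker_idx[[lin]]] <- v[marker_idx[[lin]]] + design$lineage_effect
        }
        v[tg_idx[[ti]]] <- v[tg_idx[[ti]]] + design$tissue_effect
        donor <- sprintf("%s_%s_d%d", sp, ti, d)
        smp <- sprintf("%s_%s_%s_%d", sp, sub_sp$subset[r], ti, d)
        cols[[length(cols) + 1L]] <- v
        ann[[length(ann) + 1L]] <- data.frame(
          sample = smp, subset = sub_sp$subset[r], tissue = ti,
          species = sp, donor = donor, stringsAsFactors = FALSE)
      }
    }
    vals <- do.call(cbind, cols)
    rownames(vals) <- ids
    anns <- do.call(rbind, ann)
    colnames(vals) <- anns$sample
    expression[[sp]] <- expression_matrix(vals, anns)
    marker_genes[[sp]] <- lapply(marker_idx[intersect(lineages, sub_sp$lineage)],
                                 function(ix) ids[ix])
    tissue_genes[[sp]] <- lapply(tg_idx, function(ix) ids[ix])
  }

  orthologs <- NULL
  if (all(c("human", "mouse") %in% species)) {
    n_pair <- round(design$ortholog_fraction * ng)
    paired <- sort(sample.int(ng, n_pair))
    hum <- species_gene_ids("human", ng)
    mou <- species_gene_ids("mouse", ng)
    pairs <- data.frame(human = hum[paired], mouse = mou[paired],
                        stringsAsFactors = FALSE)
    if (design$one_to_many_rate > 0 && n_pair > 0L) {
      n_extra <- round(design$one_to_many_rate * n_pair)
      unpaired <- setdiff(seq_len(ng), paired)
      n_extra <- min(n_extra, length(unpaired))
      if (n_extra > 0L) {
        dup_h <- sample(paired, n_extra)
        part_m <- sample(unpaired, n_extra)
        pairs <- rbind(pairs, data.frame(human = hum[dup_h], mouse = mou[part_m],
                                         stringsAsFactors = FALSE))
      }
    }
    orthologs <- ortholog_table(pairs)
  }

  # homologous subset pairs follow from shared lineage labels
  hom <- NULL
  lab <- unique(subsets[subsets$lineage != "none",
                        c("species", "subset", "lineage")])
  if (length(species) > 1L) {
    out <- list()
    for (lin in lineages) {
      members <- lab[lab$lineage == lin, , drop = FALSE]
      if (nrow(members) < 2L) next
      for (i in seq_len(nrow(members))) {
        for (j in seq_len(nrow(members))) {
          if (i == j || members$species[i] == members$species[j]) next
          out[[length(out) + 1L]] <- data.frame(
            species_a = members$species[i], subset_a = members$subset[i],
            species_b = members$species[j], subset_b = members$subset[j],
            lineage = lin, stringsAsFactors = FALSE)
        }
      }
    }
    if (length(out)) hom <- do.call(rbind, out)
  }

  truth <- structure(list(marker_genes = marker_genes,
                          tissue_genes = tissue_genes,
                          orthologs = orthologs,
                          homologous_subsets = hom),
                     class = "SyntheticTruth")
  list(expression = expression, orthologs = orthologs, truth = truth)
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat("SyntheticTruth\n")
  for (sp in names(x$marker_genes)) {
    cat(sprintf(" %s: %d lineages x %d markers; tissues: %s\n", sp,
                length(x$marker_genes[[sp]]),
                length(x$marker_genes[[sp]][[1L]]),
                paste(names(x$tissue_genes[[sp]]), collapse = ", ")))
  }
  if (!is.null(x$orthologs)) {
    cat(sprintf(" orthologs: %d pairs\n", nrow(x$orthologs$pairs)))
  }
  invisible(x)
}

#' Write ground truth to plain-text files
#'
#' Serializes a `SyntheticTruth` into a directory:
#' `markers_<species>.gmt` and `tissue_genes_<species>.gmt` (sets named by
#' lineage / tissue), `orthologs.tsv`, and `homologous_subsets.tsv`.
#' [read_truth()] reverses the operation losslessly.
#'
#' @param truth A `SyntheticTruth`.
#' @param dir Output directory (created if needed).
#' @param overwrite Refuse to clobber existing files unless `TRUE`.
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir, overwrite = FALSE) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    vapply(names(truth$marker_genes),
           function(sp) file.path(dir, sprintf("markers_%s.gmt", sp)), ""),
    vapply(names(truth$tissue_genes),
           function(sp) file.path(dir, sprintf("tissue_genes_%s.gmt", sp)), ""),
    file.path(dir, "orthologs.tsv"),
    file.path(dir, "homologous_subsets.tsv"))
  existing <- paths[file.exists(paths)]
  if (length(existing) && !overwrite) {
    stop("refusing to overwrite: ", paste(basename(existing), collapse = ", "))
  }
  for (sp in names(truth$marker_genes)) {
    write_gmt(truth$marker_genes[[sp]],
              file.path(dir, sprintf("markers_%s.gmt", sp)))
    write_gmt(truth$tissue_genes[[sp]],
              file.path(dir, sprintf("tissue_genes_%s.gmt", sp)))
  }
  if (!is.null(truth$orthologs)) {
    write_orthologs(truth$orthologs, file.path(dir, "orthologs.tsv"))
  } else {
    writeLines("human_gene\tmouse_gene", file.path(dir, "orthologs.tsv"))
  }
  hom <- truth$homologous_subsets
  if (is.null(hom)) {
    hom <- data.frame(species_a = character(), subset_a = character(),
                      species_b = character(), subset_b = character(),
                      lineage = character(), stringsAsFactors = FALSE)
  }
  utils::write.table(hom, file.path(dir, "homologous_subsets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read ground truth written by [write_truth()]
#'
#' @param dir Directory containing the truth files.
#' @return A `SyntheticTruth`.
#' @export
read_truth <- function(dir) {
  mk_files <- list.files(dir, "^markers_.*\\.gmt$", full.names = TRUE)
  tg_files <- list.files(dir, "^tissue_genes_.*\\.gmt$", full.names = TRUE)
  spp <- sub("^markers_(.*)\\.gmt$", "\\1", basename(mk_files))
  marker_genes <- stats::setNames(lapply(mk_files, function(f) {
    lapply(read_gmt(f), function(g) as.character(g))
  }), spp)
  spp_t <- sub("^tissue_genes_(.*)\\.gmt$", "\\1", basename(tg_files))
  tissue_genes <- stats::setNames(lapply(tg_files, function(f) {
    lapply(read_gmt(f), function(g) as.character(g))
  }), spp_t)
  orth_path <- file.path(dir, "orthologs.tsv")
  orth <- NULL
  if (file.exists(orth_path)) {
    tab <- utils::read.delim(orth_path, colClasses = "character")
    orth <- if (nrow(tab)) ortholog_table(stats::setNames(tab, c("human", "mouse")))
  }
  hom_path <- file.path(dir, "homologous_subsets.tsv")
  hom <- NULL
  if (file.exists(hom_path)) {
    tab <- utils::read.delim(hom_path, colClasses = "character")
    if (nrow(tab)) hom <- tab
  }
  structure(list(marker_genes = marker_genes, tissue_genes = tissue_genes,
                 orthologs = orth, homologous_subsets = hom),
            class = "SyntheticTruth")
}
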