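#' Directional gene signature
#'
#' A signature is an ordered up-regulated set and an ordered down-regulated
#' set of gene identifiers for one subset (or pooled lineage), the query
#' object of directional connectivity scoring. The two sets are disjoint,
#' nonempty, and free of duplicates.
#'
#' @param name Signature label.
#' @param up,down Character vectors of gene ids, ordered by decreasing /
#'   increasing ranking statistic.
#' @param source_subsets Labels of the subsets the signature was derived
#'   from.
#' @return A `GeneSignature` object.
#' @export
gene_signature <- function(name, up, down, source_subsets = name) {
  up <- as.character(up); down <- as.character(down)
  if (!length(up) || !length(down)) stop("up and down sets must be nonempty")
  if (anyDuplicated(up) || anyDuplicated(down)) {
    stop("duplicate genes within a signature set")
  }
  both <- intersect(up, down)
  if (length(both)) {
    stop("genes in both up and down sets: ", paste(both, collapse = ", "))
  }
  structure(list(name = name, up = up, down = down,
                 source_subsets = source_subsets),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature '%s': %d up / %d down (from: %s)\n",
              x$name, length(x$up), length(x$down),
              paste(x$source_subsets, collapse = ", ")))
  invisible(x)
}

#' Serialize signatures as GMT
#'
#' Each signature becomes two GMT sets, `<name>_UP` and `<name>_DN`.
#'
#' @param sigs A `GeneSignature` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sigs, path) {
  if (inherits(sigs, "GeneSignature")) sigs <- list(sigs)
  sets <- list()
  for (s in sigs) {
    desc <- paste(s$source_subsets, collapse = ",")
    sets[[paste0(s$name, "_UP")]] <- structure(s$up, description = desc)
    sets[[paste0(s$name, "_DN")]] <- structure(s$down, description = desc)
  }
  write_gmt(sets, path)
}

#' Read signatures from a GMT written by [write_signature()]
#'
#' @param path GMT path with paired `_UP`/`_DN` sets.
#' @return Named list of `GeneSignature` objects.
#' @export
read_signature <- function(path) {
  sets <- read_gmt(path)
  ups <- grep("_UP$", names(sets), value = TRUE)
  out <- list()
  for (u in ups) {
    nm <- sub("_UP$", "", u)
    d <- paste0(nm, "_DN")
    if (!d %in% names(sets)) stop("no _DN set paired with ", u)
    src <- strsplit(attr(sets[[u]], "description"), ",", fixed = TRUE)[[1L]]
    out[[nm]] <- gene_signature(nm, as.character(sets[[u]]),
                                as.character(sets[[d]]), src)
  }
  out
}

# Vectorized Welch two-sample t over matrix rows. Returns statistic, df, p.
welch_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  data.frame(statistic = stat, df = df, p.value = p,
             mean_a = m1, mean_b = m2, sd_a = sqrt(v1), sd_b = sqrt(v2))
}

#' Genes differentially expressed between two tissues
#'
#' Identifies tissue-specific genes: those differentially expressed between
#' two anatomical sources within the subsets profiled in both. Only samples
#' of matched subsets enter the test, so subset composition is balanced
#' across tissues and lineage markers are not confounded with tissue of
#' origin. Removing the returned genes (see [remove_genes()]) makes
#' signatures and dendrograms reflect subset identity rather than tissue.
#'
#' Two estimators are available. The default, `"pooled"`, runs one Welch t
#' test per gene on all matched-subset samples of `tissue_a` versus
#' `tissue_b` and applies Benjamini-Hochberg control at `alpha`.
#' `"per_subset"` tests each matched subset separately (Welch t + BH within
#' subset) and returns the union; with few replicates per subset it has
#' considerably less power than the pooled contrast.
#'
#' @param m An `ExpressionMatrix`, ideally [center_samples()]-normalized.
#' @param tissue_a,tissue_b The two tissue labels to contrast.
#' @param alpha FDR level for Benjamini-Hochberg (default 0.05).
#' @param method `"pooled"` (default) or `"per_subset"`.
#' @return Character vector of tissue-specific gene ids, in matrix row
#'   order.
#' @export
tissue_specific_genes <- function(m, tissue_a, tissue_b, alpha = 0.05,
                                  method = c("pooled", "per_subset")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  method <- match.arg(method)
  ann <- m$samples
  if (!all(c(tissue_a, tissue_b) %in% ann$tissue)) {
    stop("both tissues must be present in the annotations")
  }
  matched <- intersect(unique(ann$subset[ann$tissue == tissue_a]),
                       unique(ann$subset[ann$tissue == tissue_b]))
  if (!length(matched)) {
    stop("no subset is present in both tissues; tissue filter undefined")
  }
  for (s in matched) {
    for (ti in c(tissue_a, tissue_b)) {
      if (sum(ann$subset == s & ann$tissue == ti) < 2L) {
        stop(sprintf("subset '%s' has < 2 samples in tissue '%s'", s, ti))
      }
    }
  }
  hit <- rep(FALSE, nrow(m$values))
  if (method == "pooled") {
    a <- m$values[, ann$subset %in% matched & ann$tissue == tissue_a, drop = FALSE]
    b <- m$values[, ann$subset %in% matched & ann$tissue == tissue_b, drop = FALSE]
    res <- welch_rows(a, b)
    hit <- stats::p.adjust(res$p.value, "BH") < alpha
  } else {
    for (s in matched) {
      a <- m$values[, ann$subset == s & ann$tissue == tissue_a, drop = FALSE]
      b <- m$values[, ann$subset == s & ann$tissue == tissue_b, drop = FALSE]
      res <- welch_rows(a, b)
      hit <- hit | stats::p.adjust(res$p.value, "BH") < alpha
    }
  }
  rownames(m$values)[hit]
}

#' Drop genes from an expression matrix
#'
#' @param m An `ExpressionMatrix`.
#' @param genes Character vector of gene ids to remove; ids absent from the
#'   matrix are ignored. Row order of the remaining genes is preserved.
#' @return The filtered `ExpressionMatrix`.
#' @export
remove_genes <- function(m, genes) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  keep <- !(rownames(m$values) %in% genes)
  if (!any(keep)) stop("removing every gene leaves an empty matrix")
  m$values <- m$values[keep, , drop = FALSE]
  m
}

#' Signal-to-noise ratio per gene
#'
#' The GSEA-family ranking statistic: \eqn{(\mu_t - \mu_r) / (\sigma_t +
#' \sigma_r)} contrasting target samples against the rest, with each group
#' standard deviation floored at \eqn{\max(0.2 |\mu|, 0.2)} so that genes
#' with tiny variance cannot dominate the ranking.
#'
#' @param m An `ExpressionMatrix`.
#' @param target_samples Logical or character index of the target columns.
#' @return Named numeric vector of statistics, one per gene.
#' @export
snr_statistic <- function(m, target_samples) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.character(target_samples)) {
    target_samples <- colnames(m$values) %in% target_samples
  }
  x <- m$values[, target_samples, drop = FALSE]
  y <- m$values[, !target_samples, drop = FALSE]
  if (ncol(x) < 2L) stop("need >= 2 target samples")
  if (ncol(y) < 1L) stop("need >= 1 non-target sample")
  mt <- rowMeans(x); mr <- rowMeans(y)
  st <- apply(x, 1L, stats::sd)
  sr <- if (ncol(y) >= 2L) apply(y, 1L, stats::sd) else rep(0, nrow(m$values))
  st <- pmax(st, 0.2 * abs(mt), 0.2)
  sr <- pmax(sr, 0.2 * abs(mr), 0.2)
  stats::setNames((mt - mr) / (st + sr), rownames(m$values))
}

# rank gene ids by decreasing statistic, ties by gene id (C collation)
order_by_stat <- function(stat) {
  ids <- names(stat)
  ids[order(-stat, ids, method = "radix")]
}

#' Derive a subset signature
#'
#' Ranks every gene by signal-to-noise ratio of the target subset against
#' all other subsets (see [snr_statistic()]) and takes the `size` most
#' up-regulated genes as the up set and the `size` most down-regulated as
#' the down set. No expression-level threshold is involved; membership is
#' purely rank-based. Ties are broken by gene id, so the result is
#' deterministic and invariant to sample column order.
#'
#' @param m An `ExpressionMatrix`, typically after [remove_genes()] with
#'   the tissue-specific set.
#' @param target Subset label (annotation `subset`) to characterize.
#' @param size Genes per direction (default 150).
#' @return A [gene_signature()] named after the target. The down set is
#'   ordered most-down-regulated first.
#' @export
derive_signature <- function(m, target, size = 150) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  ann <- m$samples
  tgt <- ann$subset == target
  if (sum(tgt) < 2L) stop("target subset needs >= 2 samples: ", target)
  if (!any(!tgt)) stop("need at least one non-target subset")
  if (nrow(m$values) < 2L * size) {
    stop(sprintf("need >= %d genes for size = %d per direction", 2L * size, size))
  }
  ord <- order_by_stat(snr_statistic(m, tgt))
  gene_signature(target,
                 up = ord[seq_len(size)],
                 down = rev(ord)[seq_len(size)],
                 source_subsets = target)
}

#' Derive a pooled lineage signature
#'
#' Concatenates the samples of several subsets (possibly drawn from
#' several matrices sharing one gene space) into a single target class and
#' derives a signature against all remaining samples, exactly as
#' [derive_signature()] does for a single subset. Used to build pooled
#' lineage signatures spanning tissues.
#'
#' @param matrices An `ExpressionMatrix` or list of them; all must share
#'   the same gene space in the same order.
#' @param targets Subset labels pooled into the target class.
#' @param size Genes per direction.
#' @param name Signature name; defaults to the targets joined by `"+"`.
#' @return A [gene_signature()] with `source_subsets = targets`.
#' @export
pool_signature <- function(matrices, targets, size = 150, name = NULL) {
  if (inherits(matrices, "ExpressionMatrix")) matrices <- list(matrices)
  g0 <- rownames(matrices[[1L]]$values)
  for (m in matrices[-1L]) {
    g <- rownames(m$values)
    if (!identical(g, g0)) {
      d <- length(union(setdiff(g, g0), setdiff(g0, g)))
      stop(sprintf("matrices do not share a gene space (symmetric difference: %d%s)",
                   d, if (d == 0L) ", row order differs" else ""))
    }
  }
  vals <- do.call(cbind, lapply(matrices, function(m) m$values))
  ann <- do.call(rbind, lapply(matrices, function(m) m$samples))
  # duplicated sample ids across pooled matrices get a disambiguating suffix
  if (anyDuplicated(ann$sample)) {
    ann$sample <- make.unique(ann$sample, sep = "_rep")
    colnames(vals) <- ann$sample
  }
  pooled <- expression_matrix(vals, ann)
  present <- targets %in% ann$subset
  if (!all(present)) {
    stop("target subset(s) absent: ", paste(targets[!present], collapse = ", "))
  }
  tgt <- ann$subset %in% targets
  if (!any(!tgt)) stop("no non-target samples left to contrast against")
  if (nrow(vals) < 2L * size) {
    stop(sprintf("need >= %d genes for size = %d per direction", 2L * size, size))
  }
  if (is.null(name)) name <- paste(targets, collapse = "+")
  ord <- order_by_stat(snr_statistic(pooled, tgt))
  gene_signature(name,
                 up = ord[seq_len(size)],
                 down = rev(ord)[seq_len(size)],
                 source_subsets = targets)
}
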