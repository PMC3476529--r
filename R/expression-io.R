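#' Expression matrix with sample annotations
#'
#' Container for a log2-scale gene-by-sample intensity matrix together with
#' per-sample annotations. All downstream stages of the package (tissue-gene
#' filtering, signature derivation, connectivity scoring, clustering) operate
#' on this class.
#'
#' @param values Numeric matrix, genes in rows and samples in columns.
#'   Row names are gene identifiers, column names sample identifiers; both
#'   must be unique, and every value must be finite. Gene identifiers are
#'   treated as opaque, case-sensitive strings.
#' @param annotations Data frame with one row per sample and columns
#'   `sample`, `subset`, `tissue`, `species`, `donor`. Rows are matched to
#'   matrix columns by the `sample` column and reordered to column order.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `samples` (the annotation data frame, in
#'   column order).
#' @export
expression_matrix <- function(values, annotations) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene ids as row names and sample ids as column names")
  }
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g)) {
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s)) {
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  }
  if (!all(is.finite(values))) {
    stop("expression values must all be finite")
  }
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  required <- c("sample", "subset", "tissue", "species", "donor")
  missing_cols <- setdiff(required, names(annotations))
  if (length(missing_cols)) {
    stop("annotations lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  unannotated <- setdiff(colnames(values), annotations$sample)
  if (length(unannotated)) {
    stop("samples missing from annotations: ", paste(unannotated, collapse = ", "))
  }
  idx <- match(colnames(values), annotations$sample)
  annotations <- annotations[idx, required, drop = FALSE]
  rownames(annotations) <- NULL
  if (anyNA(annotations)) {
    stop("every sample needs all four annotations (subset, tissue, species, donor)")
  }
  structure(list(values = values, samples = annotations),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(" subsets:", paste(sort(unique(x$samples$subset)), collapse = ", "), "\n")
  cat(" tissues:", paste(sort(unique(x$samples$tissue)), collapse = ", "), "\n")
  cat(" species:", paste(sort(unique(x$samples$species)), collapse = ", "), "\n")
  invisible(x)
}

#' Gene identifiers of an expression matrix
#' @param m An `ExpressionMatrix`.
#' @return Character vector of gene ids in row order.
#' @export
gene_ids <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  rownames(m$values)
}

#' Read an expression matrix and its sample annotations
#'
#' The matrix file is tab-delimited with gene ids in the first column
#' (header `gene_id`) and one column per sample; the annotation file is
#' tab-delimited with columns `sample`, `subset`, `tissue`, `species`,
#' `donor`. Inconsistent inputs (duplicate ids, samples without
#' annotations, non-finite values) are rejected, never repaired.
#'
#' @param path Path to the tab-delimited expression matrix.
#' @param annotation_path Path to the tab-delimited annotation table.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, annotation_path) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = NA,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("matrix file needs a gene id column plus >= 1 sample")
  gid <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- gid
  ann <- utils::read.delim(annotation_path, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  expression_matrix(vals, ann)
}

#' Write an expression matrix and its sample annotations
#'
#' Output is canonical: re-reading and re-writing a file produced here
#' yields byte-identical content, which the pipeline relies on for
#' reproducibility checks.
#'
#' @param m An `ExpressionMatrix`.
#' @param path Output path for the matrix.
#' @param annotation_path Output path for the annotation table.
#' @return `m`, invisibly.
#' @export
write_expression <- function(m, path, annotation_path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  tab <- data.frame(gene_id = rownames(m$values), m$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(m$samples, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(m)
}

#' Median-center every sample
#'
#' Subtracts each sample's median intensity from that sample, the basic
#' array-style normalization used by the pipeline before differential
#' testing and connectivity scoring. Per-sample scalar offsets (donor or
#' batch effects) are removed exactly; rank orders within a sample are
#' unchanged.
#'
#' @param m An `ExpressionMatrix`.
#' @return A centered `ExpressionMatrix`.
#' @export
center_samples <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  med <- apply(m$values, 2L, stats::median)
  m$values <- sweep(m$values, 2L, med, "-")
  m
}

#' Average samples into group mean profiles
#'
#' Collapses samples into one column per group, where groups are defined by
#' one or more annotation keys. The group value of each gene is the
#' arithmetic mean over member samples.
#'
#' @param m An `ExpressionMatrix`.
#' @param group_by Character vector of annotation column names
#'   (among `subset`, `tissue`, `species`, `donor`).
#' @return An `ExpressionMatrix` with one column per group; group labels
#'   join the key values with `"."`. Annotation fields that are constant
#'   within a group keep their value, others become `"mixed"`.
#' @export
subset_mean_profile <- function(m, group_by = "subset") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  keys <- c("subset", "tissue", "species", "donor")
  bad <- setdiff(group_by, keys)
  if (length(bad)) stop("unknown grouping key(s): ", paste(bad, collapse = ", "))
  lab <- do.call(paste, c(m$samples[group_by], sep = "."))
  groups <- sort(unique(lab), method = "radix")
  vals <- vapply(groups, function(g) {
    rowMeans(m$values[, lab == g, drop = FALSE])
  }, numeric(nrow(m$values)))
  colnames(vals) <- groups
  ann <- data.frame(sample = groups, stringsAsFactors = FALSE)
  for (k in keys) {
    ann[[k]] <- vapply(groups, function(g) {
      u <- unique(m$samples[[k]][lab == g])
      if (length(u) == 1L) u else "mixed"
    }, character(1))
  }
  expression_matrix(vals, ann)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' set are dropped with a warning; a line with fewer than three fields is
#' an error reporting the line number.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (one per set, in file order);
#'   each element carries the set description in attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 gene",
                   i, length(f)))
    }
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': duplicate genes removed", f[[1L]]))
      genes <- unique(genes)
    }
    sets[[f[[1L]]]] <- structure(genes, description = f[[2L]])
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors. An element's
#'   `"description"` attribute, if present, fills the description field;
#'   otherwise the set name is repeated.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set must be named")
  }
  lines <- vapply(names(sets), function(nm) {
    genes <- sets[[nm]]
    if (!length(genes)) stop("gene set '", nm, "' is empty")
    desc <- attr(genes, "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, as.character(genes)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
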