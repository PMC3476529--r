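#' Human-mouse ortholog table
#'
#' Pairs of gene identifiers across species, possibly many-to-many.
#' Duplicate pairs are dropped with a warning; empty identifiers are an
#' error.
#'
#' @param pairs Data frame (or two-column matrix) with columns `human` and
#'   `mouse`.
#' @return An `OrthologTable`: list with `pairs` plus both lookup
#'   directions.
#' @export
ortholog_table <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) != 2L) stop("ortholog table needs exactly two columns")
  names(pairs) <- c("human", "mouse")
  pairs$human <- as.character(pairs$human)
  pairs$mouse <- as.character(pairs$mouse)
  if (any(!nzchar(pairs$human)) || any(!nzchar(pairs$mouse))) {
    stop("empty gene identifier in ortholog table")
  }
  dup <- duplicated(pairs)
  if (any(dup)) {
    warning(sprintf("%d duplicated ortholog pair(s) removed", sum(dup)))
    pairs <- pairs[!dup, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 human_to_mouse = split(pairs$mouse, pairs$human),
                 mouse_to_human = split(pairs$human, pairs$mouse)),
            class = "OrthologTable")
}

#' @export
print.OrthologTable <- function(x, ...) {
  cat(sprintf("OrthologTable: %d pairs (%d human, %d mouse genes)\n",
              nrow(x$pairs), length(x$human_to_mouse), length(x$mouse_to_human)))
  invisible(x)
}

#' Read an ortholog table
#'
#' Two-column tab-delimited file with header
#' `human_gene<TAB>mouse_gene`. Malformed lines are an error reporting
#' the line number.
#'
#' @param path File path.
#' @return An [ortholog_table()].
#' @export
read_orthologs <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty ortholog file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 2L)
  if (length(bad)) {
    stop(sprintf("ortholog file line %d has %d field(s); expected 2",
                 bad[1L], nf[bad[1L]]))
  }
  body <- fields[-1L]
  pairs <- data.frame(human = vapply(body, `[[`, "", 1L),
                      mouse = vapply(body, `[[`, "", 2L),
                      stringsAsFactors = FALSE)
  ortholog_table(pairs)
}

#' Write an ortholog table
#'
#' @param t An `OrthologTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthologs <- function(t, path) {
  stopifnot(inherits(t, "OrthologTable"))
  out <- t$pairs
  names(out) <- c("human_gene", "mouse_gene")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Translate a signature across species
#'
#' Maps the gene identifiers of a human signature into mouse gene space
#' (or the reverse) through an ortholog table. Under the default
#' `one_to_one_only` policy a gene is translated only if it has exactly
#' one ortholog which itself maps back uniquely; everything else is
#' dropped. Under `expand_all` every ortholog of every gene is included.
#' Order is inherited from the source ranking. A target gene that would
#' land in both the up and the down set is removed from both with a
#' warning, since one gene cannot be simultaneously proximal and distal
#' evidence.
#'
#' @param sig A [gene_signature()].
#' @param t An [ortholog_table()].
#' @param policy `"one_to_one_only"` (default) or `"expand_all"`.
#' @param from Source side of the table: `"human"` (default) or
#'   `"mouse"`.
#' @return A translated `GeneSignature`; attribute `"retention"` holds
#'   the fraction of source genes retained per direction. Retention below
#'   20% in either direction is an error (the mapped signature would no
#'   longer represent the source).
#' @export
map_signature <- function(sig, t, policy = c("one_to_one_only", "expand_all"),
                          from = c("human", "mouse")) {
  stopifnot(inherits(sig, "GeneSignature"), inherits(t, "OrthologTable"))
  policy <- match.arg(policy)
  from <- match.arg(from)
  fwd <- if (from == "human") t$human_to_mouse else t$mouse_to_human
  rev_ <- if (from == "human") t$mouse_to_human else t$human_to_mouse
  translate <- function(genes) {
    out <- character(0)
    src_kept <- 0L
    for (g in genes) {
      tg <- fwd[[g]]
      if (is.null(tg)) next
      if (policy == "one_to_one_only") {
        if (length(tg) != 1L) next
        back <- rev_[[tg]]
        if (length(back) != 1L) next
      }
      src_kept <- src_kept + 1L
      out <- c(out, tg)
    }
    list(genes = unique(out), retained = src_kept / length(genes))
  }
  up <- translate(sig$up)
  down <- translate(sig$down)
  clash <- intersect(up$genes, down$genes)
  if (length(clash)) {
    warning(sprintf("%d mapped gene(s) fell in both directions; removed from both",
                    length(clash)))
    up$genes <- setdiff(up$genes, clash)
    down$genes <- setdiff(down$genes, clash)
  }
  retention <- c(up = up$retained, down = down$retained)
  if (any(retention < 0.2)) {
    stop(sprintf("ortholog retention too low (up %.2f, down %.2f); signature not representative",
                 retention[["up"]], retention[["down"]]))
  }
  out <- gene_signature(sig$name, up$genes, down$genes, sig$source_subsets)
  attr(out, "retention") <- retention
  out
}
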