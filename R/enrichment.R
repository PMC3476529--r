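#' Rank a reference profile
#'
#' Orders the gene universe of one expression column by decreasing value;
#' ties are broken by gene id under C collation, so the ranking is
#' deterministic. The ranked list is the object a signature is scored
#' against.
#'
#' @param m An `ExpressionMatrix`.
#' @param column Sample (column) id or index.
#' @return A `RankedList`: list with `profile` (column id), `genes`
#'   (ids in rank order, best first) and `n` (universe size).
#' @export
rank_profile <- function(m, column) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.character(column) && !column %in% colnames(m$values)) {
    stop("no such sample column: ", column)
  }
  v <- m$values[, column]
  ids <- rownames(m$values)
  ord <- order(-v, ids, method = "radix")
  structure(list(profile = if (is.character(column)) column else colnames(m$values)[column],
                 genes = ids[ord], n = length(ids)),
            class = "RankedList")
}

#' @export
print.RankedList <- function(x, ...) {
  cat(sprintf("RankedList '%s' over %d genes; top: %s ...\n",
              x$profile, x$n, paste(utils::head(x$genes, 3), collapse = ", ")))
  invisible(x)
}

# Signed KS running-sum statistic from ascending set positions within a
# universe of size n. With t = |set| and V(j) the j-th smallest position:
#   a = max_j ( j/t - V(j)/n ),   b = max_j ( V(j)/n - (j-1)/t )
# return a if a > b else -b. This is the classic Connectivity Map form;
# positive means the set is concentrated at the top of the list.
ks_from_positions <- function(pos, n) {
  t <- length(pos)
  pos <- sort.int(pos)
  j <- seq_len(t)
  a <- max(j / t - pos / n)
  b <- max(pos / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Directional KS enrichment statistic
#'
#' Maximum signed deviation between the cumulative distribution of a gene
#' set's ranks in a ranked list and the uniform expectation: positive when
#' the set concentrates at the top of the list, negative at the bottom.
#' Values lie in (-1, 1].
#'
#' @param genes Character vector of gene ids, a nonempty strict subset of
#'   the ranked universe.
#' @param ranked A [rank_profile()] result.
#' @return Signed KS score.
#' @export
ks_statistic <- function(genes, ranked) {
  stopifnot(inherits(ranked, "RankedList"))
  genes <- as.character(genes)
  if (!length(genes)) stop("gene set is empty")
  pos <- match(genes, ranked$genes)
  if (anyNA(pos)) {
    stop("gene(s) absent from the ranked universe: ",
         paste(genes[is.na(pos)], collapse = ", "))
  }
  if (length(pos) >= ranked$n) stop("gene set must be a strict subset of the universe")
  ks_from_positions(pos, ranked$n)
}

# connectivity score from precomputed KS values: zero when the up and down
# sets deviate in the same direction, else their difference
combine_ks <- function(ks_up, ks_down) {
  if (sign(ks_up) == sign(ks_down)) 0 else ks_up - ks_down
}

#' Directional connectivity score of a signature against a profile
#'
#' Scores the up and the down set separately with [ks_statistic()] and
#' combines them: if both deviate in the same direction the profile is
#' called unrelated (score 0); otherwise the score is `ks_up - ks_down`,
#' positive for transcriptionally proximal profiles (up set high, down set
#' low) and negative for distal, inverse ones. Range \eqn{[-2, 2]}.
#'
#' @param sig A [gene_signature()].
#' @param ranked A [rank_profile()] result covering all signature genes.
#' @return Raw connectivity score.
#' @export
connectivity_score <- function(sig, ranked) {
  stopifnot(inherits(sig, "GeneSignature"))
  combine_ks(ks_statistic(sig$up, ranked), ks_statistic(sig$down, ranked))
}

#' Scale raw connectivity scores to \eqn{[-1, 1]}
#'
#' Positive scores are divided by the maximum positive score and negative
#' scores by the absolute minimum, yielding scaled dimensionless
#' quantities comparable within one analysis run; zeros are unchanged.
#' Sign and weak ordering are preserved and the operation is idempotent.
#'
#' @param raw Numeric vector of raw scores.
#' @return Scaled scores in \eqn{[-1, 1]}.
#' @export
scale_scores <- function(raw) {
  if (!length(raw)) stop("need at least one score")
  out <- raw
  if (any(raw > 0)) out[raw > 0] <- raw[raw > 0] / max(raw[raw > 0])
  if (any(raw < 0)) out[raw < 0] <- raw[raw < 0] / abs(min(raw[raw < 0]))
  out
}

# B null connectivity scores for a signature of the given set sizes: the
# null permutes gene-set membership, drawing |up| + |down| distinct genes
# uniformly from the universe. Note the distribution depends only on
# (n_up, n_down, n), not on the profile being scored.
null_scores <- function(n_up, n_down, n, B) {
  vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n_up + n_down)
    combine_ks(ks_from_positions(idx[seq_len(n_up)], n),
               ks_from_positions(idx[-seq_len(n_up)], n))
  }, numeric(1))
}

#' Permutation significance of a connectivity score
#'
#' Compares the observed score of a signature against `B` scores of random
#' signatures with matching up/down sizes drawn without replacement from
#' the ranked universe (a permutation between gene signatures). The
#' two-sided, add-one empirical p-value
#' \deqn{p = (1 + \#\{|null| \ge |obs|\}) / (B + 1)}
#' has attainable minimum \eqn{1/(B+1)} and equals 1 when the observed
#' score is 0.
#'
#' @param sig A [gene_signature()].
#' @param ranked A [rank_profile()] result.
#' @param B Number of permutations (default 1000).
#' @param seed Optional integer seed; the caller's RNG state is restored
#'   on exit.
#' @return List with `p.value`, `observed` and `n_permutations`.
#' @export
permutation_test <- function(sig, ranked, B = 1000, seed = NULL) {
  stopifnot(inherits(sig, "GeneSignature"), inherits(ranked, "RankedList"), B >= 1)
  if (length(sig$up) + length(sig$down) > ranked$n) {
    stop("universe smaller than |up| + |down|")
  }
  obs <- connectivity_score(sig, ranked)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  nulls <- null_scores(length(sig$up), length(sig$down), ranked$n, B)
  list(p.value = (1 + sum(abs(nulls) >= abs(obs))) / (B + 1),
       observed = obs, n_permutations = B)
}

#' Score a signature against every reference profile
#'
#' Runs the full connectivity analysis of one signature against an
#' annotated reference matrix: each reference sample (or each subset mean
#' profile when `per_sample = FALSE`) is ranked, scored, and the raw
#' scores are scaled jointly across the whole run so they are comparable
#' panel-wide. Signature genes absent from the reference universe are
#' dropped with a warning; losing more than half of either set is an
#' error.
#'
#' By default profiles are ranked by relative expression: each gene is
#' centered on its mean across the reference cohort before ranking
#' (`gene_center = TRUE`). Absolute single-channel intensities are
#' dominated by per-gene baseline (probe affinity) that is common to all
#' samples, which blurs the subset-specific rank shifts the connectivity
#' score reads; centering ranks each profile by what is high or low *for
#' that gene*. Set `gene_center = FALSE` to rank raw values.
#'
#' Per-score permutation p-values reuse one set of `B` null scores for all
#' profiles in the run: the gene-membership null depends only on the set
#' sizes and the universe size, not on which profile is scored, so this is
#' exact and merely avoids redundant draws.
#'
#' @param sig A [gene_signature()].
#' @param refs An `ExpressionMatrix` of reference profiles with `subset`
#'   annotations.
#' @param per_sample Score every sample (default) or one mean profile per
#'   subset.
#' @param B Permutations for the significance test.
#' @param seed Integer seed for the permutation null.
#' @param gene_center Rank profiles by expression relative to the per-gene
#'   cohort mean (default `TRUE`).
#' @return An `EnrichmentResult`: list with `scores` (data frame: query,
#'   subset, sample, raw_score, scaled_score, p_value), `by_subset` (data
#'   frame: query, subset, n_profiles, mean_scaled, median_p) ordered by
#'   decreasing mean scaled score, and `n_permutations`.
#' @export
enrichment_table <- function(sig, refs, per_sample = TRUE, B = 1000, seed = 1L,
                             gene_center = TRUE) {
  stopifnot(inherits(sig, "GeneSignature"), inherits(refs, "ExpressionMatrix"))
  if (gene_center) {
    refs$values <- refs$values - rowMeans(refs$values)
  }
  universe <- rownames(refs$values)
  lost <- setdiff(c(sig$up, sig$down), universe)
  if (length(lost)) {
    total <- length(sig$up) + length(sig$down)
    if (length(lost) == total) stop("no signature gene is present in the references")
    if (length(lost) > 0.5 * total) {
      stop(sprintf("%d of %d signature genes absent from references (> 50%%)",
                   length(lost), total))
    }
    warning(sprintf("dropping %d signature gene(s) absent from references",
                    length(lost)))
    sig <- gene_signature(sig$name, setdiff(sig$up, lost),
                          setdiff(sig$down, lost), sig$source_subsets)
  }
  mat <- if (per_sample) refs else subset_mean_profile(refs, "subset")
  cols <- colnames(mat$values)
  ranked <- lapply(cols, function(cc) rank_profile(mat, cc))
  raw <- vapply(ranked, function(r) connectivity_score(sig, r), numeric(1))
  scaled <- scale_scores(raw)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nulls <- null_scores(length(sig$up), length(sig$down), nrow(refs$values), B)
  pvals <- vapply(raw, function(x) (1 + sum(abs(nulls) >= abs(x))) / (B + 1),
                  numeric(1))
  scores <- data.frame(query = sig$name,
                       subset = mat$samples$subset,
                       sample = cols,
                       raw_score = raw,
                       scaled_score = scaled,
                       p_value = pvals,
                       stringsAsFactors = FALSE)
  subs <- sort(unique(scores$subset), method = "radix")
  by_subset <- data.frame(
    query = sig$name,
    subset = subs,
    n_profiles = vapply(subs, function(s) sum(scores$subset == s), integer(1)),
    mean_scaled = vapply(subs, function(s) {
      mean(scores$scaled_score[scores$subset == s])
    }, numeric(1)),
    median_p = vapply(subs, function(s) {
      stats::median(scores$p_value[scores$subset == s])
    }, numeric(1)),
    stringsAsFactors = FALSE)
  by_subset <- by_subset[order(-by_subset$mean_scaled, by_subset$subset,
                               method = "radix"), , drop = FALSE]
  rownames(by_subset) <- NULL
  structure(list(scores = scores, by_subset = by_subset, n_permutations = B),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult: query '%s' vs %d profiles in %d subsets (B = %d)\n",
              x$scores$query[1L], nrow(x$scores), nrow(x$by_subset),
              x$n_permutations))
  print(x$by_subset, row.names = FALSE)
  invisible(x)
}

#' Strip chart of connectivity scores by reference subset
#'
#' Scatter of per-profile scaled scores with the subset mean marked,
#' subsets ordered by decreasing mean scaled score.
#'
#' @param x An `EnrichmentResult`.
#' @param ... Passed to [graphics::stripchart()].
#' @return `x`, invisibly.
#' @export
plot_enrichment <- function(x, ...) {
  stopifnot(inherits(x, "EnrichmentResult"))
  lv <- rev(x$by_subset$subset)
  f <- factor(x$scores$subset, levels = lv)
  graphics::stripchart(x$scores$scaled_score ~ f, vertical = FALSE,
                       pch = 1, method = "jitter", jitter = 0.08,
                       xlab = "scaled connectivity score", ylab = "",
                       main = x$scores$query[1L], las = 1, xlim = c(-1, 1), ...)
  graphics::abline(v = 0, lty = 3)
  means <- rev(x$by_subset$mean_scaled)
  graphics::points(means, seq_along(lv), pch = 18, cex = 1.6)
  invisible(x)
}
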