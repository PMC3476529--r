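# fixtures built in code: a tiny labelled matrix and a reduced cohort design

tiny_matrix <- function() {
  vals <- matrix(c(5, 1, 9,
                   6, 2, 8), nrow = 3,
                 dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  ann <- data.frame(sample = c("s1", "s2"),
                    subset = c("X", "Y"), tissue = "blood",
                    species = "human", donor = c("d1", "d2"),
                    stringsAsFactors = FALSE)
  expression_matrix(vals, ann)
}

# labelled random matrix with several subsets/tissues, no planted signal
noise_matrix <- function(n_genes = 60, seed = 42) {
  set.seed(seed)
  subs <- expand.grid(subset = c("A", "B", "C"), tissue = c("blood", "skin"),
                      rep = 1:3, stringsAsFactors = FALSE)
  vals <- matrix(rnorm(n_genes * nrow(subs), 8, 1), nrow = n_genes,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 sprintf("s%02d", seq_len(nrow(subs)))))
  ann <- data.frame(sample = colnames(vals), subset = subs$subset,
                    tissue = subs$tissue, species = "human",
                    donor = paste0(subs$tissue, "_d", subs$rep),
                    stringsAsFactors = FALSE)
  expression_matrix(vals, ann)
}

# scaled-down two-species design for fast pipeline tests
small_design <- function(seed = 1, ...) {
  default_cohort_design(seed = seed, n_genes = 600,
                        n_marker_genes_per_lineage = 40,
                        n_tissue_genes_per_tissue = 50, ...)
}

# independent exhaustive running-sum oracle for the signed KS statistic:
# walk every list position, tracking the set ECDF against uniform
ks_oracle <- function(pos, n) {
  t <- length(pos)
  inset <- logical(n)
  inset[pos] <- TRUE
  a <- 0; b <- -Inf
  hits <- 0
  for (i in seq_len(n)) {
    b <- max(b, i / n - hits / t)   # deviation just before counting a hit
    if (inset[i]) hits <- hits + 1
    a <- max(a, hits / t - i / n)
  }
  if (a > b) a else -b
}

ranked_from_ids <- function(ids) {
  structure(list(profile = "fixed", genes = ids, n = length(ids)),
            class = "RankedList")
}
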