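# Shared fixture builders and independent oracles for the test suite.

# Build an annotated experiment from a matrix and (tissue, stage, genotype)
# vectors, one entry per sample.
make_exp <- function(values, accession = "EXP1", tissue = NULL,
                     stage = NULL, genotype = NULL) {
  n <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%02d", 1:n)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  samples <- NULL
  if (!is.null(tissue)) {
    samples <- as_sample_sheet(data.frame(
      sample_id = colnames(values),
      tissue = tissue,
      stage = if (is.null(stage)) "1 DAP" else stage,
      genotype = if (is.null(genotype)) "WT" else genotype,
      stringsAsFactors = FALSE))
  }
  expression_experiment(values, accession, samples = samples)
}

# Random gene x sample matrix with optional missing values.
random_matrix <- function(genes, samples, na_frac = 0) {
  m <- matrix(rnorm(genes * samples, mean = 8, sd = 2), genes, samples,
              dimnames = list(sprintf("g%02d", 1:genes),
                              sprintf("s%02d", 1:samples)))
  if (na_frac > 0) {
    idx <- which(runif(length(m)) < na_frac)
    m[idx] <- NA_real_
  }
  m
}

# Independent brute-force mutual-rank oracle: per-pair correlations from the
# textbook product-moment formula and ranks from base rank() applied to each
# gene's explicitly assembled correlation list.
oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  dx <- x - mean(x); dy <- y - mean(y)
  den <- sqrt(sum(dx^2)) * sqrt(sum(dy^2))
  if (den == 0) return(NA_real_)
  sum(dx * dy) / den
}

oracle_mr_matrix <- function(values, min_pairs = 4L) {
  G <- nrow(values)
  C <- matrix(NA_real_, G, G, dimnames = list(rownames(values),
                                              rownames(values)))
  for (i in seq_len(G)) {
    for (j in seq_len(G)) {
      if (i == j) next
      n_ok <- sum(!is.na(values[i, ]) & !is.na(values[j, ]))
      if (n_ok < min_pairs) next
      C[i, j] <- oracle_pearson(values[i, ], values[j, ])
    }
  }
  R <- matrix(NA_real_, G, G, dimnames = dimnames(C))
  for (i in seq_len(G)) {
    v <- C[i, ]
    idx <- which(!is.na(v))
    if (length(idx) == 0L) next
    R[i, idx] <- rank(-v[idx], ties.method = "average")
  }
  sqrt(R * t(R))
}

# Brute-force scan oracle for the exclusivity screen in its degenerate
# limit (ratio 0, floor below everything): a gene passes iff it has data in
# some target group and in no off-target group.
oracle_target_only <- function(atl, gene, target_tissues) {
  in_target <- FALSE; in_off <- FALSE
  for (e in atl$experiments) {
    if (!gene %in% rownames(e$values)) next
    v <- e$values[gene, ]
    tgt <- e$samples$tissue %in% target_tissues
    if (any(!is.na(v[tgt]))) in_target <- TRUE
    if (any(!is.na(v[!tgt]))) in_off <- TRUE
  }
  in_target && !in_off
}
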