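#' Pearson correlations of one bait gene against all other genes
#'
#' Correlations use replicate-level samples (not condition means) with
#' pairwise-complete observations. Genes whose pairwise-complete overlap with
#' the bait is below `min_pairs`, or whose values have zero variance on that
#' overlap, are excluded and listed with a reason.
#'
#' @param experiment An [expression_experiment()].
#' @param bait Bait gene id, present in the experiment.
#' @param min_pairs Minimum pairwise-complete observations per correlation
#'   (default 4).
#' @return A list of class `correlation_vector` with elements `accession`,
#'   `bait`, `r` (named numeric, one entry per retained gene), `n_pairs`
#'   (named integer) and `excluded` (data frame gene_id, reason).
#' @export
correlation_vector <- function(experiment, bait, min_pairs = 4L) {
  x <- experiment$values
  if (!bait %in% rownames(x)) {
    stop("bait '", bait, "' not present in experiment ", experiment$accession)
  }
  others <- setdiff(rownames(x), bait)
  bv <- x[bait, ]
  r <- rep(NA_real_, length(others))
  np <- integer(length(others))
  reason <- character(length(others))
  for (i in seq_along(others)) {
    gv <- x[others[i], ]
    ok <- !is.na(bv) & !is.na(gv)
    np[i] <- sum(ok)
    if (np[i] < min_pairs) {
      reason[i] <- "too_few_pairs"
      next
    }
    if (stats::sd(bv[ok]) == 0 || stats::sd(gv[ok]) == 0) {
      reason[i] <- "zero_variance"
      next
    }
    r[i] <- stats::cor(bv[ok], gv[ok])
  }
  keep <- reason == ""
  structure(
    list(accession = experiment$accession, bait = bait,
         r = stats::setNames(r[keep], others[keep]),
         n_pairs = stats::setNames(np[keep], others[keep]),
         excluded = data.frame(gene_id = others[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE)),
    class = "correlation_vector"
  )
}

# Gene x gene Pearson matrix over pairwise-complete samples, with pairs
# failing min_pairs set to NA and the diagonal set to NA (self-pairs are
# never ranked). Constant genes drop out naturally as NA correlations.
correlation_matrix <- function(experiment, min_pairs = 4L) {
  x <- t(experiment$values)  # samples x genes for stats::cor
  suppressWarnings(C <- stats::cor(x, use = "pairwise.complete.obs"))
  npairs <- crossprod(!is.na(x))
  C[npairs < min_pairs] <- NA_real_
  diag(C) <- NA_real_
  C
}

# Average rank of value v0 within vector v (descending order, average-rank
# ties), counting only non-NA competitors. Returns NA when v0 is NA.
rank_descending_of <- function(v0, v) {
  if (is.na(v0)) {
    return(NA_real_)
  }
  v <- v[!is.na(v)]
  sum(v > v0) + (sum(v == v0) + 1) / 2
}

#' Mutual rank of a bait/gene pair within one experiment
#'
#' MR is the geometric mean of the two reciprocal correlation ranks:
#' `sqrt(rank(bait -> gene) * rank(gene -> bait))`, where `rank(a -> b)` is
#' the rank of b in a's correlation ordering (descending Pearson r, self
#' excluded, average-rank ties). Low MR means strong mutual coexpression.
#'
#' @inheritParams correlation_vector
#' @param gene Partner gene id.
#' @return The MR value, or `NA` when the pair is unrankable (insufficient
#'   overlap or zero variance).
#' @export
mutual_rank <- function(experiment, bait, gene, min_pairs = 4L) {
  for (g in c(bait, gene)) {
    if (!g %in% rownames(experiment$values)) {
      stop("gene '", g, "' not present in experiment ", experiment$accession)
    }
  }
  if (bait == gene) {
    stop("self-pairs are excluded from mutual ranking")
  }
  C <- correlation_matrix(experiment, min_pairs = min_pairs)
  r_bg <- rank_descending_of(C[bait, gene], C[bait, ])
  r_gb <- rank_descending_of(C[gene, bait], C[gene, ])
  sqrt(r_bg * r_gb)
}

#' Full mutual-rank matrix of an experiment
#'
#' Symmetric gene x gene matrix of mutual ranks; `NA` marks unrankable pairs
#' and the diagonal.
#'
#' @inheritParams correlation_vector
#' @return Numeric matrix with gene ids as dimnames.
#' @export
mutual_rank_matrix <- function(experiment, min_pairs = 4L) {
  C <- correlation_matrix(experiment, min_pairs = min_pairs)
  G <- nrow(C)
  R <- matrix(NA_real_, G, G, dimnames = dimnames(C))
  for (i in seq_len(G)) {
    ci <- C[i, ]
    valid <- ci[!is.na(ci)]
    if (length(valid) == 0L) next
    # rank of every j in gene i's descending ordering, vectorized
    R[i, ] <- vapply(ci, function(v) {
      if (is.na(v)) NA_real_ else sum(valid > v) + (sum(valid == v) + 1) / 2
    }, numeric(1))
  }
  sqrt(R * t(R))
}

# Per-experiment MRs of one bait against every other gene; O(G^2) using the
# precomputed correlation matrix. Returns named numeric (NA = unrankable).
bait_mr_vector <- function(C, bait) {
  genes <- rownames(C)
  others <- setdiff(genes, bait)
  cb <- C[bait, ]
  valid_b <- cb[!is.na(cb)]
  r_bg <- vapply(cb[others], function(v) {
    if (is.na(v)) NA_real_ else sum(valid_b > v) + (sum(valid_b == v) + 1) / 2
  }, numeric(1))
  r_gb <- vapply(others, function(g) {
    rank_descending_of(C[g, bait], C[g, ])
  }, numeric(1))
  stats::setNames(sqrt(r_bg * r_gb), others)
}

#' Combine per-experiment mutual ranks into one record
#'
#' The default policy is the geometric mean of the contributing experiments'
#' MRs (equivalently the arithmetic mean in log space); `"max"` is the
#' conservative worst-case alternative. Coverage is the number of experiments
#' contributing a finite MR; records below `min_coverage` are flagged.
#'
#' @param mrs Named numeric vector of per-experiment MR values (names =
#'   accessions); `NA` entries do not contribute.
#' @param policy `"geometric_mean"` or `"max"`.
#' @param min_coverage Minimum number of contributing experiments required
#'   for the combined MR to be considered scoreable (default 1).
#' @return List with `combined_mr` (NA when coverage is 0 or below
#'   `min_coverage`), `coverage`, and `per_experiment`.
#' @export
combine_across_experiments <- function(mrs,
                                       policy = c("geometric_mean", "max"),
                                       min_coverage = 1L) {
  policy <- match.arg(policy)
  if (length(mrs) == 0L) {
    stop("no per-experiment MR values supplied")
  }
  contributing <- mrs[!is.na(mrs)]
  coverage <- length(contributing)
  combined <- if (coverage == 0L || coverage < min_coverage) {
    NA_real_
  } else if (policy == "geometric_mean") {
    exp(mean(log(contributing)))
  } else {
    max(contributing)
  }
  list(combined_mr = combined, coverage = coverage, per_experiment = mrs)
}

#' Mutual-rank records of bait genes across an atlas
#'
#' For every bait and every other gene in the atlas, computes the
#' per-experiment MRs and their cross-experiment combination. By default a
#' gene must be scoreable in every experiment in which the bait itself is
#' measured (`min_coverage = "bait"`); pass an integer to relax this.
#'
#' @param atl A [atlas()].
#' @param baits Character vector of bait gene ids.
#' @param min_pairs Minimum pairwise-complete observations per correlation.
#' @param policy Combination policy, see [combine_across_experiments()].
#' @param min_coverage `"bait"` (default) or an integer.
#' @return Data frame with columns `bait_id`, `gene_id`, one `mr_<accession>`
#'   column per experiment, `combined_mr`, `coverage`.
#' @export
mutual_rank_records <- function(atl, baits, min_pairs = 4L,
                                policy = c("geometric_mean", "max"),
                                min_coverage = "bait") {
  policy <- match.arg(policy)
  stopifnot(inherits(atl, "coex_atlas"), length(baits) >= 1L)
  acc <- names(atl$experiments)
  Cs <- lapply(atl$experiments, correlation_matrix, min_pairs = min_pairs)
  out <- list()
  for (bait in baits) {
    present <- vapply(atl$experiments,
                      function(e) bait %in% rownames(e$values), logical(1))
    if (!any(present)) {
      stop("bait '", bait, "' absent from every experiment")
    }
    per_exp <- lapply(acc[present], function(a) bait_mr_vector(Cs[[a]], bait))
    names(per_exp) <- acc[present]
    genes <- setdiff(atl$gene_universe, bait)
    mr_mat <- matrix(NA_real_, length(genes), length(acc),
                     dimnames = list(genes, acc))
    for (a in names(per_exp)) {
      v <- per_exp[[a]]
      mr_mat[names(v), a] <- v
    }
    mc <- if (identical(min_coverage, "bait")) sum(present) else
      as.integer(min_coverage)
    coverage <- rowSums(!is.na(mr_mat))
    logm <- log(mr_mat)
    combined <- if (policy == "geometric_mean") {
      exp(rowMeans(logm, na.rm = TRUE))
    } else {
      suppressWarnings(apply(mr_mat, 1, max, na.rm = TRUE))
    }
    combined[coverage == 0 | coverage < mc] <- NA_real_
    df <- data.frame(bait_id = bait, gene_id = genes,
                     stringsAsFactors = FALSE)
    for (a in acc) df[[paste0("mr_", a)]] <- mr_mat[, a]
    df$combined_mr <- combined
    df$coverage <- as.integer(coverage)
    out[[bait]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select candidate genes under a joint MR threshold
#'
#' A gene is a candidate when its combined MR is strictly below `threshold`
#' against every bait. Members are sorted by ascending worst-case
#' (max-over-baits) combined MR, ties broken lexicographically by gene id;
#' baits themselves are excluded.
#'
#' @param records Record data frame from [mutual_rank_records()].
#' @param baits Character vector of bait ids that must all be satisfied.
#' @param threshold Strict upper bound on combined MR (e.g. 20 or 50).
#' @return An object of class `candidate_set`: list with `baits`,
#'   `threshold`, and `members` (data frame gene_id, one `mr_vs_<bait>`
#'   column per bait, `max_mr`).
#' @export
select_candidates <- function(records, baits, threshold) {
  stopifnot(is.data.frame(records), threshold > 0)
  recs <- records[records$bait_id %in% baits &
                    !(records$gene_id %in% baits), , drop = FALSE]
  wide <- stats::reshape(
    recs[, c("bait_id", "gene_id", "combined_mr")],
    direction = "wide", idvar = "gene_id", timevar = "bait_id",
    v.names = "combined_mr"
  )
  names(wide) <- sub("^combined_mr\\.", "mr_vs_", names(wide))
  mr_cols <- paste0("mr_vs_", baits)
  missing <- setdiff(mr_cols, names(wide))
  for (col in missing) wide[[col]] <- NA_real_
  wide <- wide[, c("gene_id", mr_cols), drop = FALSE]
  mrs <- as.matrix(wide[, mr_cols, drop = FALSE])
  pass <- rowSums(is.na(mrs)) == 0L & apply(mrs < threshold, 1, all)
  members <- wide[pass, , drop = FALSE]
  members$max_mr <- if (nrow(members)) apply(
    as.matrix(members[, mr_cols, drop = FALSE]), 1, max) else numeric(0)
  members <- members[order(members$max_mr, members$gene_id), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(baits = baits, threshold = threshold, members = members),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> MR < ", x$threshold, " against ",
      length(x$baits), " bait(s): ", nrow(x$members), " gene(s)\n", sep = "")
  if (nrow(x$members)) print(utils::head(x$members, 10))
  invisible(x)
}

#' Candidate-set membership as a character vector
#' @param x A `candidate_set`.
#' @return Character vector of member gene ids.
#' @export
candidate_genes <- function(x) {
  stopifnot(inherits(x, "candidate_set"))
  x$members$gene_id
}
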