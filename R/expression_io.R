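#' Construct an expression experiment
#'
#' Container for one experiment's normalized (log2-scale, RMA-style)
#' expression values plus optional sample annotations. The package performs
#' no normalization: values are assumed already normalized on a log2 scale.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). `NA` marks missing values;
#'   all non-missing values must be finite.
#' @param accession Opaque experiment identifier.
#' @param samples Optional sample sheet (see [read_sample_sheet()]) covering
#'   every sample id in `values`.
#' @return An object of class `expression_experiment`.
#' @export
expression_experiment <- function(values, accession, samples = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("'values' must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         " (see collapse_duplicates())")
  }
  if (any(!is.finite(values) & !is.na(values))) {
    stop("non-finite expression values present (accession ", accession, ")")
  }
  if (!is.null(samples)) {
    missing <- setdiff(sample_ids, samples$sample_id)
    if (length(missing) > 0L) {
      stop("sample ids absent from the sample sheet: ",
           paste(missing, collapse = ", "))
    }
    samples <- samples[match(sample_ids, samples$sample_id), , drop = FALSE]
    rownames(samples) <- NULL
  }
  structure(
    list(accession = as.character(accession), values = values,
         samples = samples),
    class = "expression_experiment"
  )
}

#' @export
print.expression_experiment <- function(x, ...) {
  cat("<expression_experiment> ", x$accession, ": ",
      nrow(x$values), " genes x ", ncol(x$values), " samples",
      if (!is.null(x$samples)) " (annotated)", "\n", sep = "")
  invisible(x)
}

#' Gene identifiers of an experiment or atlas
#' @param x An `expression_experiment` or `coex_atlas`.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(x) {
  if (inherits(x, "expression_experiment")) {
    return(rownames(x$values))
  }
  if (inherits(x, "coex_atlas")) {
    return(x$gene_universe)
  }
  stop("unsupported class")
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row whose first column is the gene-id column and whose
#' remaining columns are sample ids, then one row per gene. Cells equal to
#' `missing_token` become flagged missing values; any other non-numeric cell
#' is a parse error. Duplicate gene rows are handled by
#' [collapse_duplicates()] under `duplicate_rule`.
#'
#' @param path Path to the TSV file.
#' @param accession Experiment identifier to attach.
#' @param missing_token Token marking a missing value (default `"NA"`).
#' @param duplicate_rule One of `"max_mean"`, `"first"`, `"error"`.
#' @return An [expression_experiment()].
#' @export
read_expression_matrix <- function(path, accession,
                                   missing_token = "NA",
                                   duplicate_rule = c("max_mean", "first",
                                                      "error")) {
  duplicate_rule <- match.arg(duplicate_rule)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L) {
    stop("empty expression matrix file: ", path)
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L) {
    stop("malformed header in ", path,
         ": expected a gene-id column plus at least one sample column")
  }
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in header of ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != length(header))) {
    stop("row(s) ", paste(which(nfield != length(header))[1], collapse = ", "),
         " of ", path, " do not have ", length(header), " fields")
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  cells <- matrix(unlist(lapply(fields, `[`, -1L)),
                  nrow = length(fields), byrow = TRUE)
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  is_missing <- cells == missing_token
  bad <- is.na(num) & !is_missing
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-numeric cell '", cells[i[1], i[2]], "' (gene ", ids[i[1]],
         ", sample ", sample_ids[i[2]], ") is not the missing token '",
         missing_token, "'")
  }
  num[is_missing] <- NA_real_
  dimnames(num) <- list(ids, sample_ids)
  exp <- structure(
    list(accession = as.character(accession), values = num, samples = NULL),
    class = "expression_experiment"
  )
  exp <- collapse_duplicates(exp, rule = duplicate_rule)
  # re-run full validation now that gene ids are unique
  expression_experiment(exp$values, accession)
}

#' Collapse duplicate gene rows
#'
#' Array probe sets commonly map many-to-one onto loci; this collapses
#' duplicate gene ids to a single row. Under `"max_mean"` the retained row is
#' the one with the highest mean across samples (the conventional
#' highest-signal probe set); `"first"` keeps the first row in file order;
#' `"error"` refuses duplicates.
#'
#' @param experiment An [expression_experiment()].
#' @param rule One of `"max_mean"`, `"first"`, `"error"`.
#' @return An `expression_experiment` with one row per gene id.
#' @export
collapse_duplicates <- function(experiment,
                                rule = c("max_mean", "first", "error")) {
  rule <- match.arg(rule)
  ids <- rownames(experiment$values)
  if (!anyDuplicated(ids)) {
    return(experiment)
  }
  if (rule == "error") {
    stop("duplicate gene ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  keep <- if (rule == "first") {
    !duplicated(ids)
  } else {
    means <- rowMeans(experiment$values, na.rm = TRUE)
    # stable: among ties on mean, the earlier row wins
    ord <- order(factor(ids, levels = unique(ids)), -means)
    picked <- ord[!duplicated(ids[ord])]
    seq_along(ids) %in% picked
  }
  out <- experiment
  out$values <- experiment$values[keep, , drop = FALSE]
  out
}

#' Read a sample sheet
#'
#' Tab-delimited annotation with columns `sample_id`, `tissue`, `stage`,
#' `genotype` and optionally `replicate`. Stage labels must be numeric
#' DAP-style labels (`"3 DAP"`, `"3-4 DAP"`, `"2 to 4 DAP"`) or members of
#' `vocabulary`. When the replicate column is absent, replicates are numbered
#' 1..k in file order within each (tissue, stage, genotype) group.
#'
#' @param path Path to the TSV file.
#' @param vocabulary Named numeric vector mapping non-numeric stage labels to
#'   ordering midpoints; see [default_stage_vocabulary()].
#' @return A `data.frame` of class `sample_sheet` with an added
#'   `stage_midpoint` column defining the stage order.
#' @export
read_sample_sheet <- function(path, vocabulary = default_stage_vocabulary()) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  as_sample_sheet(df, vocabulary = vocabulary)
}

#' Validate a data frame as a sample sheet
#'
#' @param df Data frame with columns `sample_id`, `tissue`, `stage`,
#'   `genotype` and optionally `replicate`.
#' @inheritParams read_sample_sheet
#' @return A validated `sample_sheet`.
#' @export
as_sample_sheet <- function(df, vocabulary = default_stage_vocabulary()) {
  required <- c("sample_id", "tissue", "stage", "genotype")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in sample sheet")
  }
  mid <- stage_midpoint(df$stage, vocabulary)
  if (anyNA(mid)) {
    stop("unknown stage label(s): ",
         paste(unique(df$stage[is.na(mid)]), collapse = ", "),
         " (not numeric and not in the stage vocabulary)")
  }
  df$stage_midpoint <- mid
  if (is.null(df$replicate)) {
    grp <- interaction(df$tissue, df$stage, df$genotype, drop = TRUE)
    df$replicate <- stats::ave(seq_len(nrow(df)), grp, FUN = seq_along)
  } else {
    df$replicate <- as.integer(df$replicate)
    if (anyNA(df$replicate) || any(df$replicate < 1L)) {
      stop("replicate indices must be integers >= 1")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Bundle experiments into an atlas
#'
#' @param experiments List of [expression_experiment()] objects with unique
#'   accessions. Gene identifiers must already be harmonized across
#'   experiments (the package attempts no probe-annotation lookup).
#' @return An object of class `coex_atlas` with the union gene universe and a
#'   per-experiment presence matrix.
#' @export
atlas <- function(experiments) {
  if (length(experiments) < 1L) {
    stop("an atlas needs at least one experiment")
  }
  ok <- vapply(experiments, inherits, logical(1), "expression_experiment")
  if (!all(ok)) {
    stop("all atlas members must be expression_experiment objects")
  }
  acc <- vapply(experiments, `[[`, character(1), "accession")
  if (anyDuplicated(acc)) {
    stop("duplicate experiment accessions: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  names(experiments) <- acc
  universe <- sort(unique(unlist(lapply(experiments,
                                        function(e) rownames(e$values)))))
  presence <- vapply(experiments,
                     function(e) universe %in% rownames(e$values),
                     logical(length(universe)))
  presence <- matrix(presence, nrow = length(universe),
                     dimnames = list(universe, acc))
  structure(
    list(experiments = experiments, gene_universe = universe,
         presence = presence),
    class = "coex_atlas"
  )
}

#' @export
print.coex_atlas <- function(x, ...) {
  cat("<coex_atlas> ", length(x$experiments), " experiment(s), ",
      length(x$gene_universe), " genes in the union universe\n", sep = "")
  for (e in x$experiments) print(e)
  invisible(x)
}

# Deterministic numeric formatting shared by all table writers so that
# identical runs give byte-identical files and read/write round-trips agree
# to 6 significant digits.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.6g", v)
  }, character(1))
  out
}

write_tsv_deterministic <- function(df, path) {
  con <- file(path, open = "wb")  # binary: fixed "\n" on every platform
  on.exit(close(con))
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- format_num(df[[j]])
  for (j in which(!num)) out[[j]] <- as.character(df[[j]])
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out) > 0L) {
    writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
  }
  invisible(path)
}

#' Write a mutual-rank candidate/record table
#'
#' Rows are ordered by ascending combined MR, ties broken by gene id then
#' bait id (lexicographic), so output is deterministic. Numeric values are
#' written with 6 significant digits and round-trip through
#' [read_candidate_table()].
#'
#' @param records Data frame of mutual-rank records
#'   (see [mutual_rank_records()]); may be empty.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_candidate_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  required <- c("bait_id", "gene_id", "combined_mr", "coverage")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L) {
    stop("record table is missing column(s): ", paste(missing, collapse = ", "))
  }
  ord <- order(records$combined_mr, records$gene_id, records$bait_id)
  write_tsv_deterministic(records[ord, , drop = FALSE], path)
}

#' Read back a candidate/record table written by [write_candidate_table()]
#' @param path TSV path.
#' @return Data frame of mutual-rank records.
#' @export
read_candidate_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  for (col in c("bait_id", "gene_id")) {
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  }
  if ("coverage" %in% names(df)) df$coverage <- as.integer(df$coverage)
  df
}

#' Write a specificity-screen table
#'
#' Columns `gene_id`, `status`, `exclusive`, `peak_stage`, `label`, rows in
#' lexicographic gene-id order. Round-trips through
#' [read_specificity_table()].
#'
#' @param calls Data frame of specificity calls (see [screen_family()]).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_specificity_table <- function(calls, path) {
  stopifnot(is.data.frame(calls))
  required <- c("gene_id", "status", "exclusive", "peak_stage", "label")
  missing <- setdiff(required, names(calls))
  if (length(missing) > 0L) {
    stop("specificity table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  calls <- calls[order(calls$gene_id), required, drop = FALSE]
  calls$exclusive <- ifelse(is.na(calls$exclusive), "NA",
                            ifelse(calls$exclusive, "yes", "no"))
  write_tsv_deterministic(calls, path)
}

#' Read back a specificity table written by [write_specificity_table()]
#' @param path TSV path.
#' @return Data frame of specificity calls.
#' @export
read_specificity_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  df$exclusive <- ifelse(df$exclusive == "NA", NA, df$exclusive == "yes")
  df
}

#' Write an expression experiment back to the TSV interchange format
#'
#' Inverse of [read_expression_matrix()] (plus [write_sample_sheet()] for the
#' annotations); used by the synthetic-atlas generator to materialize
#' simulated experiments on disk.
#'
#' @param experiment An [expression_experiment()].
#' @param path Output TSV path for the matrix.
#' @return The path, invisibly.
#' @export
write_expression_matrix <- function(experiment, path) {
  df <- data.frame(gene_id = rownames(experiment$values),
                   experiment$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_deterministic(df, path)
}

#' Write a sample sheet to TSV
#' @param samples A `sample_sheet`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  cols <- c("sample_id", "tissue", "stage", "genotype", "replicate")
  write_tsv_deterministic(as.data.frame(samples)[, cols, drop = FALSE], path)
}
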