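write_lines_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

test_that("a well-formed matrix parses with genes, samples and flagged missings", {
  p <- write_lines_tsv(c("gene_id\tsA\tsB",
                         "g1\t1.5\t2.5",
                         "g2\tNA\t4.0",
                         "g3\t5.0\t6.0"))
  e <- read_expression_matrix(p, "EXP1")
  expect_s3_class(e, "expression_experiment")
  expect_equal(rownames(e$values), c("g1", "g2", "g3"))
  expect_equal(colnames(e$values), c("sA", "sB"))
  # the missing count equals the count of NA tokens in the file
  n_tokens <- sum(vapply(strsplit(readLines(p)[-1], "\t"),
                         function(f) sum(f[-1] == "NA"), integer(1)))
  expect_equal(sum(is.na(e$values)), n_tokens)
  expect_equal(e$values["g1", "sB"], 2.5)
})

test_that("malformed inputs are rejected with informative errors", {
  expect_error(
    read_expression_matrix(write_lines_tsv(c("gene_id\tsA\tsA",
                                             "g1\t1\t2")), "E"),
    "duplicate sample ids")
  expect_error(
    read_expression_matrix(write_lines_tsv(c("gene_id", "g1")), "E"),
    "malformed header")
  expect_error(
    read_expression_matrix(write_lines_tsv(c("gene_id\tsA",
                                             "g1\tlow")), "E"),
    "not the missing token")
  # a configurable missing token makes the same file valid
  e <- read_expression_matrix(
    write_lines_tsv(c("gene_id\tsA", "g1\tlow")), "E",
    missing_token = "low")
  expect_true(is.na(e$values["g1", "sA"]))
  expect_error(expression_experiment(
    matrix(c(1, Inf), 2, 1, dimnames = list(c("a", "b"), "s1")), "E"),
    "non-finite")
})

test_that("duplicate gene rows collapse per the configured rule", {
  vals <- matrix(c(4, 6, 6, 8, 1, 2), 3, 2, byrow = TRUE,
                 dimnames = list(c("G", "G", "H"), c("s1", "s2")))
  raw <- structure(list(accession = "E", values = vals, samples = NULL),
                   class = "expression_experiment")
  kept <- collapse_duplicates(raw, "max_mean")
  expect_equal(unname(kept$values["G", ]), c(6, 8))  # mean 7 beats mean 5
  expect_equal(nrow(kept$values), 2L)
  expect_equal(colnames(kept$values), colnames(vals))
  first <- collapse_duplicates(raw, "first")
  expect_equal(unname(first$values["G", ]), c(4, 6))
  expect_error(collapse_duplicates(raw, "error"), "duplicate gene ids")
  # no duplicates: identity under every rule
  nodup <- make_exp(random_matrix(4, 3))
  for (rule in c("max_mean", "first", "error")) {
    expect_identical(collapse_duplicates(nodup, rule)$values, nodup$values)
  }
})

test_that("three-way duplicates under rule 'first' match the line-order oracle", {
  set.seed(11)
  lines <- c("gene_id\ts1\ts2\ts3")
  vals <- round(matrix(runif(15, 1, 10), 5, 3), 3)
  ids <- c("G", "A", "G", "G", "B")
  for (i in 1:5) lines <- c(lines, paste(c(ids[i], vals[i, ]), collapse = "\t"))
  p <- write_lines_tsv(lines)
  e <- read_expression_matrix(p, "E", duplicate_rule = "first")
  # naive oracle: first file-order row per id
  expect_equal(unname(e$values["G", ]), vals[1, ])
  expect_equal(sort(rownames(e$values)), c("A", "B", "G"))
})

test_that("sample sheets validate stages and auto-number absent replicates", {
  p <- write_lines_tsv(c("sample_id\ttissue\tstage\tgenotype\treplicate",
                         "s1\tleaf\t7 DAP\tWT\t1",
                         "s2\tleaf\t1 DAP\tWT\t1",
                         "s3\tleaf\t4 DAP\tWT\t1"))
  sheet <- read_sample_sheet(p)
  expect_equal(order(sheet$stage_midpoint), c(2L, 3L, 1L))  # 1 < 4 < 7
  expect_error(
    read_sample_sheet(write_lines_tsv(
      c("sample_id\tstage\tgenotype", "s1\t1 DAP\tWT"))),
    "missing column")
  expect_error(
    read_sample_sheet(write_lines_tsv(
      c("sample_id\ttissue\tstage\tgenotype", "s1\tleaf\tmystery\tWT"))),
    "unknown stage label")
  # replicate auto-numbering follows file order within each group
  p2 <- write_lines_tsv(c("sample_id\ttissue\tstage\tgenotype",
                          "s1\tleaf\t1 DAP\tWT",
                          "s2\troot\t1 DAP\tWT",
                          "s3\tleaf\t1 DAP\tWT",
                          "s4\tleaf\t1 DAP\tWT"))
  sheet2 <- read_sample_sheet(p2)
  expect_equal(sheet2$replicate, c(1L, 1L, 2L, 3L))
})

test_that("interval and vocabulary stage labels order by midpoint", {
  mids <- stage_midpoint(c("before anthesis", "1-2 DAP", "3-4 DAP",
                           "2 to 4 DAP", "5-10 DAP", "11-20 DAP", "7 DAP"))
  expect_equal(mids, c(-1, 1.5, 3.5, 3, 7.5, 15.5, 7))
  expect_true(all(diff(mids[c(1, 2, 3, 5, 6)]) > 0))
})

test_that("candidate tables round-trip with deterministic ordering", {
  set.seed(3)
  recs <- data.frame(
    bait_id = rep("B1", 10),
    gene_id = sprintf("g%02d", sample(1:99, 10)),
    mr_E1 = round(runif(10, 1, 80), 4),
    combined_mr = round(runif(10, 1, 80), 4),
    coverage = sample(1:3, 10, replace = TRUE),
    stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".tsv")
  write_candidate_table(recs, p)
  back <- read_candidate_table(p)
  ord <- order(recs$combined_mr, recs$gene_id, recs$bait_id)
  expect_equal(back$gene_id, recs$gene_id[ord])
  expect_equal(back$combined_mr, recs$combined_mr[ord], tolerance = 1e-6)
  expect_equal(back$coverage, recs$coverage[ord])
  # equal combined MR: lexicographic gene-id tie-break
  ties <- data.frame(bait_id = "B1", gene_id = c("zz", "aa"),
                     combined_mr = c(5, 5), coverage = 1L,
                     stringsAsFactors = FALSE)
  write_candidate_table(ties, p)
  expect_equal(read_candidate_table(p)$gene_id, c("aa", "zz"))
  # empty input: header-only file
  write_candidate_table(recs[0, ], p)
  expect_length(readLines(p), 1L)
})

test_that("specificity tables round-trip including NA verdicts", {
  calls <- data.frame(
    gene_id = c("g2", "g1", "g3"),
    status = c("called", "called", "not_measured"),
    exclusive = c(TRUE, FALSE, NA),
    peak_stage = c("3-4 DAP", NA, NA),
    label = c("3-4 DAP, endosperm", "", ""),
    stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".tsv")
  write_specificity_table(calls, p)
  back <- read_specificity_table(p)
  expect_equal(back$gene_id, c("g1", "g2", "g3"))
  expect_equal(back$exclusive, c(FALSE, TRUE, NA))
  expect_equal(back$label[back$gene_id == "g2"], "3-4 DAP, endosperm")
})

test_that("expression matrices round-trip through write and read", {
  set.seed(5)
  e <- make_exp(round(random_matrix(6, 4, na_frac = 0.1), 4), "RT1")
  p <- tempfile(fileext = ".tsv")
  write_expression_matrix(e, p)
  back <- read_expression_matrix(p, "RT1")
  expect_equal(back$values, e$values, tolerance = 1e-6)
})

test_that("validation is insensitive to row and column permutation", {
  set.seed(9)
  m <- round(random_matrix(5, 4), 4)
  lines <- c(paste(c("gene_id", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], m[i, ]), collapse = "\t"),
               character(1)))
  perm_rows <- sample(nrow(m)); perm_cols <- sample(ncol(m))
  mp <- m[perm_rows, perm_cols]
  lines2 <- c(paste(c("gene_id", colnames(mp)), collapse = "\t"),
              vapply(seq_len(nrow(mp)), function(i)
                paste(c(rownames(mp)[i], mp[i, ]), collapse = "\t"),
                character(1)))
  e1 <- read_expression_matrix(write_lines_tsv(lines), "E")
  e2 <- read_expression_matrix(write_lines_tsv(lines2), "E")
  canon <- function(e) e$values[sort(rownames(e$values)),
                                sort(colnames(e$values))]
  expect_equal(canon(e1), canon(e2))
})

test_that("atlases track the union gene universe and presence flags", {
  e1 <- make_exp(random_matrix(3, 3), "A")
  m2 <- random_matrix(2, 3)
  rownames(m2) <- c("g02", "g99")
  e2 <- make_exp(m2, "B")
  atl <- atlas(list(e1, e2))
  expect_setequal(gene_ids(atl), c("g01", "g02", "g03", "g99"))
  expect_true(atl$presence["g02", "A"] && atl$presence["g02", "B"])
  expect_false(atl$presence["g99", "A"])
  expect_error(atlas(list(e1, e1)), "duplicate experiment accessions")
  expect_error(atlas(list()), "at least one experiment")
})
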