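# Small two-experiment atlas with a tissue contrast: EXP-A surveys leaf +
# endosperm, EXP-B is an endosperm time-course.
toy_atlas <- function(gene_rows_a, gene_rows_b) {
  a <- make_exp(gene_rows_a, "EXP-A",
                tissue = c("leaf", "leaf", "leaf",
                           "endosperm", "endosperm", "endosperm"),
                stage = c(rep("vegetative", 3), rep("3-4 DAP", 3)))
  b <- make_exp(gene_rows_b, "EXP-B",
                tissue = rep("endosperm", 6),
                stage = rep(c("3-4 DAP", "5-10 DAP"), each = 3))
  atlas(list(a, b))
}

test_that("condition profiles report group means and standard errors", {
  vals <- matrix(c(4, 4, 4, 2, 4, 9), 1, 6,
                 dimnames = list("g1", paste0("s", 1:6)))
  e <- make_exp(vals, "E",
                tissue = c(rep("leaf", 3), rep("endosperm", 3)),
                stage = c(rep("vegetative", 3), "3-4 DAP", "3-4 DAP",
                          "5 DAP"))
  prof <- condition_profile(e, "g1")
  leaf <- prof[prof$tissue == "leaf", ]
  expect_equal(leaf$mean, 4)
  expect_equal(leaf$se, 0)
  pair <- prof[prof$stage == "3-4 DAP", ]  # replicates (2, 4)
  expect_equal(pair$mean, 3)
  expect_equal(pair$se, 1)                 # sd sqrt(2) / sqrt(2)
  single <- prof[prof$stage == "5 DAP", ]  # n = 1: SE not available
  expect_equal(single$n, 1L)
  expect_true(is.na(single$se))
  expect_error(condition_profile(e, "absent"), "not present")
})

test_that("all-missing groups are omitted from profiles", {
  vals <- matrix(c(NA, NA, 5, 6), 1, 4, dimnames = list("g1", paste0("s", 1:4)))
  e <- make_exp(vals, "E", tissue = c("leaf", "leaf", "root", "root"))
  prof <- condition_profile(e, "g1")
  expect_equal(prof$tissue, "root")
})

test_that("an endosperm-peaked gene is exclusive and a flat gene is not", {
  # g1: floor-level everywhere except endosperm 3-4 DAP; g2: housekeeping
  a_vals <- rbind(g1 = c(4, 4.1, 3.9, 10, 10.2, 9.8),
                  g2 = c(8, 8.1, 7.9, 8, 8.2, 7.8),
                  g3 = c(12, 12, 12, 4, 4, 4))
  b_vals <- rbind(g1 = c(10, 10, 10, 7.5, 7.6, 7.4),
                  g2 = c(8, 8, 8, 8, 8, 8),
                  g3 = c(4, 4, 4, 4, 4, 4))
  colnames(a_vals) <- paste0("a", 1:6); colnames(b_vals) <- paste0("b", 1:6)
  atl <- toy_atlas(a_vals, b_vals)
  rule <- specificity_rule(expression_floor = 5)
  c1 <- classify_specificity(atl, "g1", rule)
  expect_true(c1$exclusive)
  expect_equal(c1$peak_stage, "3-4 DAP")
  expect_equal(c1$label, "3-4 DAP, 5-10 DAP, endosperm")
  c2 <- classify_specificity(atl, "g2", rule)
  expect_false(c2$exclusive)
  c3 <- classify_specificity(atl, "g3", rule)  # leaf gene
  expect_false(c3$exclusive)
})

test_that("peak-stage ties break toward the earlier stage", {
  a_vals <- matrix(c(4, 4, 4, 9, 9, 9), 1, 6, dimnames = list("g1", NULL))
  b_vals <- matrix(c(9, 9, 9, 9, 9, 9), 1, 6, dimnames = list("g1", NULL))
  atl <- toy_atlas(a_vals, b_vals)
  call <- classify_specificity(atl, "g1", specificity_rule(expression_floor = 5))
  expect_equal(call$peak_stage, "3-4 DAP")
})

test_that("genes without any tissue contrast are indeterminate, absent ones not measured", {
  b <- make_exp(matrix(c(9, 9, 9), 1, 3, dimnames = list("g1", NULL)),
                "EXP-B", tissue = rep("endosperm", 3),
                stage = rep("3-4 DAP", 3))
  atl <- atlas(list(b))
  call <- classify_specificity(atl, "g1", specificity_rule(expression_floor = 5))
  expect_equal(call$status, "indeterminate")
  expect_true(is.na(call$exclusive))
  scr <- screen_family(atl, c("g1", "ghost"))
  expect_equal(scr$status, c("indeterminate", "not_measured"))
})

test_that("classification is invariant to sample order and all-missing samples", {
  set.seed(81)
  a_vals <- rbind(g1 = c(4, 4.2, 3.8, 10, 9.9, 10.1),
                  g2 = runif(6, 6, 9))
  colnames(a_vals) <- paste0("a", 1:6)
  b_vals <- rbind(g1 = c(10, 10, 10, 4, 4, 4), g2 = runif(6, 6, 9))
  colnames(b_vals) <- paste0("b", 1:6)
  atl <- toy_atlas(a_vals, b_vals)
  rule <- specificity_rule(expression_floor = 5)
  base <- classify_specificity(atl, "g1", rule)

  perm <- sample(6)
  a2 <- make_exp(a_vals[, perm], "EXP-A",
                 tissue = c("leaf", "leaf", "leaf", "endosperm",
                            "endosperm", "endosperm")[perm],
                 stage = c(rep("vegetative", 3), rep("3-4 DAP", 3))[perm])
  atl2 <- atlas(list(a2, atl$experiments[["EXP-B"]]))
  shuffled <- classify_specificity(atl2, "g1", rule)
  expect_equal(shuffled$exclusive, base$exclusive)
  expect_equal(shuffled$label, base$label)

  # appending an all-missing sample changes nothing
  a3_vals <- cbind(a_vals, extra = c(NA, NA))
  a3 <- make_exp(a3_vals, "EXP-A",
                 tissue = c("leaf", "leaf", "leaf", "endosperm",
                            "endosperm", "endosperm", "root"),
                 stage = c(rep("vegetative", 3), rep("3-4 DAP", 3),
                           "vegetative"))
  atl3 <- atlas(list(a3, atl$experiments[["EXP-B"]]))
  padded <- classify_specificity(atl3, "g1", rule)
  expect_equal(padded$exclusive, base$exclusive)
  expect_equal(padded$label, base$label)
})

test_that("raising an off-target group can never create exclusivity", {
  base_leaf <- c(4, 4, 4)
  for (bump in c(0, 2, 4, 8)) {
    a_vals <- matrix(c(base_leaf + bump, 10, 10, 10), 1, 6,
                     dimnames = list("g1", NULL))
    b_vals <- matrix(rep(10, 6), 1, 6, dimnames = list("g1", NULL))
    atl <- toy_atlas(a_vals, b_vals)
    call <- classify_specificity(atl, "g1",
                                 specificity_rule(expression_floor = 5))
    if (bump == 0) {
      expect_true(call$exclusive)
      verdict_prev <- TRUE
    } else {
      # monotone: once lost, exclusivity never returns as leaf rises
      expect_true(verdict_prev || !call$exclusive)
      verdict_prev <- call$exclusive && verdict_prev
    }
  }
  # explicit check at the top bump
  expect_false(call$exclusive)
})

test_that("ratio 0 with an unbounded floor reduces to target-only expression", {
  set.seed(91)
  genes <- sprintf("g%02d", 1:8)
  a_vals <- matrix(runif(48, 2, 12), 8, 6, dimnames = list(genes, NULL))
  # g03 and g07: literally no off-target signal (missing outside endosperm)
  a_vals[c(3, 7), 1:3] <- NA
  b_vals <- matrix(runif(48, 2, 12), 8, 6, dimnames = list(genes, NULL))
  atl <- toy_atlas(a_vals, b_vals)
  rule <- specificity_rule(expression_floor = -Inf, exclusivity_ratio = 0)
  scr <- screen_family(atl, genes, rule)
  oracle <- vapply(genes, oracle_target_only, logical(1), atl = atl,
                   target_tissues = rule$target_tissues)
  expect_equal(scr$exclusive, unname(oracle))
  expect_setequal(scr$gene_id[which(scr$exclusive)], c("g03", "g07"))
})

test_that("genotype comparisons report means, SEs and linear ratios", {
  vals <- matrix(c(5, 6, 7, 5, 6, 7), 1, 6, dimnames = list("g1", NULL))
  e <- make_exp(vals, "E", tissue = "grain", stage = "7 DAP",
                genotype = rep(c("WT", "mut"), each = 3))
  cmp <- compare_genotypes(e, "g1", "WT", "mut")
  expect_equal(cmp$ratio, 1)

  vals2 <- matrix(c(6, 6, 6, 5, 5, 5), 1, 6, dimnames = list("g1", NULL))
  e2 <- make_exp(vals2, "E", tissue = "grain", stage = "7 DAP",
                 genotype = rep(c("WT", "mut"), each = 3))
  cmp2 <- compare_genotypes(e2, "g1", "WT", "mut")
  expect_equal(cmp2$ratio, 0.5)  # log2 means 6 vs 5
  expect_equal(compare_genotypes(e2, "g1", "WT", "mut",
                                 scale = "linear")$ratio, 5 / 6)

  set.seed(101)
  vals3 <- matrix(rnorm(6, 8), 1, 6, dimnames = list("g1", NULL))
  e3 <- make_exp(vals3, "E", tissue = "grain", stage = "7 DAP",
                 genotype = rep(c("WT", "mut"), each = 3))
  cmp3 <- compare_genotypes(e3, "g1", "WT", "mut")
  expect_equal(cmp3$a$mean, mean(vals3[1, 1:3]))
  expect_equal(cmp3$b$se, sd(vals3[1, 4:6]) / sqrt(3))
  expect_equal(cmp3$ratio, 2^(mean(vals3[1, 4:6]) - mean(vals3[1, 1:3])))
  expect_error(compare_genotypes(e3, "g1", "WT", "nope"), "no non-missing")
})
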