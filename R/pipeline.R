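#' Build a run configuration
#'
#' A run is driven either by on-disk experiments (`experiments` = list of
#' lists with `accession`, `matrix`, `samples` paths) or by the synthetic
#' generator (`simulate = TRUE`, using `seed` and any spec overrides in
#' `simulate_args`). Flags given here override config-file values when the
#' two are merged by [read_run_config()].
#'
#' @param experiments List of experiment path sets, or `NULL` when
#'   simulating.
#' @param simulate Logical; generate the atlas with [make_atlas()].
#' @param simulate_args Named list of [synthetic_atlas_spec()] overrides.
#' @param baits Character vector of bait gene ids; when `NULL` and
#'   simulating, the planted baits are used.
#' @param family Character vector of family gene ids for the specificity
#'   screen; when `NULL` and simulating, the planted module is used.
#' @param rule_args Named list of [specificity_rule()] overrides.
#' @param thresholds Joint MR thresholds (default `c(20, 50)`).
#' @param policy Cross-experiment combination policy.
#' @param min_pairs Minimum pairwise-complete observations per correlation.
#' @param min_coverage `"bait"` or an integer; see [mutual_rank_records()].
#' @param seed Integer seed for simulation.
#' @param out_dir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(experiments = NULL, simulate = is.null(experiments),
                       simulate_args = list(), baits = NULL, family = NULL,
                       rule_args = list(), thresholds = c(20, 50),
                       policy = c("geometric_mean", "max"), min_pairs = 4L,
                       min_coverage = "bait", seed = 1L,
                       out_dir = tempfile("coexmr_run_")) {
  policy <- match.arg(policy)
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  structure(
    list(experiments = experiments, simulate = simulate,
         simulate_args = simulate_args, baits = baits, family = family,
         rule_args = rule_args, thresholds = sort(as.numeric(thresholds)),
         policy = policy, min_pairs = as.integer(min_pairs),
         min_coverage = min_coverage, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]. Arguments passed
#' through `...` override file values.
#'
#' @param path YAML config path.
#' @param ... Overrides, as in [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, cfg)
}

# Resolve config -> (atlas, truth-or-NULL, baits, family).
resolve_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (isTRUE(config$simulate)) {
    args <- config$simulate_args
    args$seed <- config$seed
    sim <- make_atlas(do.call(synthetic_atlas_spec, args))
    atl <- sim$atlas
    truth <- sim$truth
    baits <- if (is.null(config$baits))
      truth$gene_id[truth$is_bait] else config$baits
    family <- if (is.null(config$family))
      truth$gene_id[truth$is_module] else config$family
  } else {
    if (length(config$experiments) < 1L) {
      stop("config must list experiments or set simulate = TRUE")
    }
    exps <- lapply(config$experiments, function(e) {
      x <- read_expression_matrix(e$matrix, e$accession)
      sheet <- read_sample_sheet(e$samples)
      expression_experiment(x$values, e$accession, samples = sheet)
    })
    atl <- atlas(exps)
    truth <- NULL
    if (is.null(config$baits)) stop("config must name bait genes")
    baits <- config$baits
    family <- config$family
  }
  list(atlas = atl, truth = truth, baits = baits, family = family)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the expression-exclusivity screen stage
#'
#' @param config A [run_config()].
#' @param inputs Optional pre-resolved inputs (internal reuse).
#' @return The specificity-call data frame; also written to
#'   `specificity.tsv` under the output directory.
#' @export
run_screen <- function(config, inputs = resolve_inputs(config)) {
  run_stage("screen", {
    if (is.null(inputs$family)) stop("no family genes configured")
    rule <- do.call(specificity_rule, config$rule_args)
    calls <- screen_family(inputs$atlas, inputs$family, rule)
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_specificity_table(calls, file.path(config$out_dir,
                                             "specificity.tsv"))
    calls
  })
}

#' Run the mutual-rank stage
#'
#' @inheritParams run_screen
#' @return List with `records` (full MR table) and `candidates` (one
#'   [select_candidates()] result per configured threshold). Writes
#'   `mutual_ranks.tsv` and `candidates_mr<threshold>.tsv`.
#' @export
run_rank <- function(config, inputs = resolve_inputs(config)) {
  run_stage("rank", {
    records <- mutual_rank_records(inputs$atlas, inputs$baits,
                                   min_pairs = config$min_pairs,
                                   policy = config$policy,
                                   min_coverage = config$min_coverage)
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_candidate_table(records, file.path(config$out_dir,
                                             "mutual_ranks.tsv"))
    candidates <- lapply(config$thresholds, function(th) {
      cs <- select_candidates(records, inputs$baits, th)
      write_candidate_table(
        data.frame(bait_id = "ALL", gene_id = cs$members$gene_id,
                   combined_mr = cs$members$max_mr,
                   coverage = NA_integer_,
                   stringsAsFactors = FALSE),
        file.path(config$out_dir, sprintf("candidates_mr%g.tsv", th)))
      cs
    })
    names(candidates) <- sprintf("mr%g", config$thresholds)
    list(records = records, candidates = candidates)
  })
}

#' Run the evaluation stage against planted truth
#'
#' @inheritParams run_screen
#' @param rank_out Optional result of [run_rank()] to reuse.
#' @return Named list of [recovery_metrics()] per threshold; written to
#'   `metrics.json`.
#' @export
run_evaluate <- function(config, inputs = resolve_inputs(config),
                         rank_out = run_rank(config, inputs)) {
  run_stage("evaluate", {
    if (is.null(inputs$truth)) {
      stop("evaluation needs planted truth (simulated runs only)")
    }
    metrics <- lapply(rank_out$candidates, recovery_metrics,
                      truth = inputs$truth)
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    metrics
  })
}

#' Run the full pipeline: simulate/load, screen, rank, evaluate
#'
#' Deterministic for a fixed config (including seed): repeated runs produce
#' byte-identical output files. Every stage's outputs and the design
#' decisions in force (tie rule, combination policy, thresholds, rule
#' parameters) are echoed into `run_report.json`.
#'
#' @param config A [run_config()].
#' @return List with `screen`, `rank`, `metrics` (NULL when no truth), and
#'   `report`.
#' @export
run_all <- function(config) {
  inputs <- run_stage("input", resolve_inputs(config))
  if (isTRUE(config$simulate)) {
    run_stage("simulate",
              write_atlas(list(atlas = inputs$atlas, truth = inputs$truth),
                          file.path(config$out_dir, "atlas")))
  }
  screen_out <- run_screen(config, inputs)
  rank_out <- run_rank(config, inputs)
  metrics <- if (!is.null(inputs$truth)) {
    run_evaluate(config, inputs, rank_out)
  } else {
    NULL
  }
  outputs <- list.files(config$out_dir, recursive = TRUE)
  row_counts <- c(
    specificity = nrow(screen_out),
    mutual_ranks = nrow(rank_out$records),
    stats::setNames(vapply(rank_out$candidates,
                           function(cs) nrow(cs$members), integer(1)),
                    paste0("candidates_", names(rank_out$candidates)))
  )
  report <- list(
    config = list(
      simulate = config$simulate, seed = config$seed,
      baits = inputs$baits, family = inputs$family,
      thresholds = config$thresholds, policy = config$policy,
      min_pairs = config$min_pairs, min_coverage = config$min_coverage,
      rule = unclass(do.call(specificity_rule, config$rule_args))[
        c("target_tissues", "exclusivity_ratio", "peak_window")]
    ),
    decisions = list(
      correlation = "Pearson, replicate-level samples, pairwise-complete",
      ranking = "descending r, self excluded, average-rank ties",
      combination = config$policy,
      thresholds = "strict '<' at every threshold"
    ),
    outputs = outputs,
    row_counts = as.list(row_counts),
    complete = TRUE
  )
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(screen = screen_out, rank = rank_out, metrics = metrics,
       report = report)
}
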