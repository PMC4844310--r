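#' Default synthetic experiment designs
#'
#' Three heterogeneous designs mirroring a typical public-array mix for
#' grain development: a tissue-diverse survey (leaf, root, seedling, embryo,
#' endosperm), a dense daily caryopsis time-course over early development,
#' and a reproductive series spanning floral organs (anther, pistil, lemma)
#' plus an endosperm series from before anthesis to late grain fill. The
#' mix exercises the cross-experiment combination and coverage logic on
#' designs that differ in both tissues and staging, and gives the
#' exclusivity screen two independent tissue contrasts.
#'
#' @return Named list of designs; each design is a list with `accession` and
#'   a `groups` data frame (tissue, stage, genotype, replicates).
#' @export
default_atlas_designs <- function() {
  list(
    list(accession = "SIM-TD",
         groups = data.frame(
           tissue = c("leaf", "root", "seedling", "embryo", "endosperm"),
           stage = c("vegetative", "vegetative", "vegetative",
                     "3-4 DAP", "3-4 DAP"),
           genotype = "WT", replicates = 3L,
           stringsAsFactors = FALSE)),
    list(accession = "SIM-TC",
         groups = data.frame(
           tissue = "caryopsis",
           stage = paste(1:10, "DAP"),
           genotype = "WT", replicates = 3L,
           stringsAsFactors = FALSE)),
    list(accession = "SIM-RS",
         groups = data.frame(
           tissue = c("anther", "pistil", "lemma",
                      rep("endosperm", 5)),
           stage = c(rep("before anthesis", 3),
                     "before anthesis", "1-2 DAP", "3-4 DAP", "5-10 DAP",
                     "11-20 DAP"),
           genotype = "WT", replicates = 3L,
           stringsAsFactors = FALSE))
  )
}

#' Specification of a synthetic expression atlas
#'
#' Describes a multi-experiment atlas containing a planted module of
#' mutually coexpressed, endosperm-exclusive genes (including the baits)
#' against a background of unrelated genes, on a log2 scale.
#'
#' The planted module follows one shared stage curve: maximal over the
#' 3-4 DAP window, declining linearly to baseline by 10 DAP, silent before
#' 3 DAP and outside the target tissues. Module coexpression has two
#' sources controlled by `rho`: the shared stage profile enters each gene
#' with weight `rho` (blended with a gene-private profile at weight
#' `1 - rho`), and within-group replicate noise contains a shared per-sample
#' latent factor with loading `sqrt(rho)`. Setting `rho = 0` is the null
#' control: the module structure is absent and the "module" genes are drawn
#' from the background model (their truth exclusivity flags are FALSE).
#'
#' @param n_background_genes Number of background genes (default 500).
#' @param n_module_genes Module size including baits (default 6).
#' @param n_baits Number of baits inside the module (default 3).
#' @param rho Module correlation strength in `(0, 1]`, or exactly 0 for the
#'   null control (default 0.95).
#' @param noise_sd Replicate-level Gaussian noise sd in log2 units
#'   (default 0.2).
#' @param leakage Off-target leakage of module genes as a fraction of their
#'   amplitude (default 0).
#' @param baseline Baseline log2 level (default 4).
#' @param amplitude Peak height above baseline in log2 units (default 6).
#' @param designs Experiment designs, see [default_atlas_designs()].
#' @param seed Integer seed; the atlas is a deterministic function of the
#'   spec including the seed.
#' @return A list of class `synthetic_atlas_spec`.
#' @export
synthetic_atlas_spec <- function(n_background_genes = 500L,
                                 n_module_genes = 6L,
                                 n_baits = 3L,
                                 rho = 0.95,
                                 noise_sd = 0.2,
                                 leakage = 0,
                                 baseline = 4,
                                 amplitude = 6,
                                 designs = default_atlas_designs(),
                                 seed = 1L) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1] (0 = null control)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_baits < 1L || n_baits > n_module_genes) {
    stop("n_baits must be between 1 and n_module_genes")
  }
  for (d in designs) {
    if (nrow(d$groups) < 2L) stop("every design needs >= 2 groups")
    if (any(d$groups$replicates < 1L)) stop("designs need >= 1 replicate")
  }
  structure(
    list(n_background_genes = as.integer(n_background_genes),
         n_module_genes = as.integer(n_module_genes),
         n_baits = as.integer(n_baits), rho = rho, noise_sd = noise_sd,
         leakage = leakage, baseline = baseline, amplitude = amplitude,
         designs = designs, seed = as.integer(seed)),
    class = "synthetic_atlas_spec"
  )
}

# Planted stage profile, shared by the whole module: 1 in the 3-4 DAP peak
# window, linear decline to baseline by 10 DAP, absent before 3 DAP. A
# single shared curve keeps the module tightly mutually correlated; shape
# heterogeneity between module genes would dilute exactly the coexpression
# signal the module is planted to carry.
planted_template <- function(midpoint) {
  ifelse(midpoint >= 3 & midpoint <= 4, 1,
         ifelse(midpoint > 4 & midpoint < 10, (10 - midpoint) / 6, 0))
}

#' Generate a synthetic atlas with planted truth
#'
#' Deterministic under a fixed spec (including its seed): the same spec
#' always yields an identical atlas. The caller's RNG state is left
#' untouched.
#'
#' @param spec A [synthetic_atlas_spec()].
#' @return List with `atlas` (a [atlas()] of annotated experiments) and
#'   `truth` (data frame: gene_id, is_module, is_bait, exclusive,
#'   peak_window, label).
#' @export
make_atlas <- function(spec = synthetic_atlas_spec()) {
  stopifnot(inherits(spec, "synthetic_atlas_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  n_mod <- spec$n_module_genes
  bait_ids <- sprintf("BAIT_%02d", seq_len(spec$n_baits))
  planted_ids <- if (n_mod > spec$n_baits)
    sprintf("PLANTED_%02d", seq_len(n_mod - spec$n_baits)) else character(0)
  module_ids <- c(bait_ids, planted_ids)
  bg_ids <- sprintf("BG_%04d", seq_len(spec$n_background_genes))
  genes <- c(module_ids, bg_ids)
  target_tissues <- c("caryopsis", "endosperm")
  null_control <- spec$rho == 0

  # per-gene module parameters (shared across experiments)
  amp <- spec$amplitude * stats::runif(n_mod, 0.8, 1.2)
  # background model: per-gene overall level plus moderate per-group jitter
  # (unrelated genes vary modestly and incoherently between conditions).
  # Jitter is capped well below the planted amplitude and carries no
  # systematic condition preference: a background gene with a strong,
  # reproducible preference for the target condition would be coexpressed
  # with the module and hence not an unrelated gene at all.
  n_bg <- spec$n_background_genes
  bg_level <- spec$baseline + stats::runif(n_bg, 0, 7)
  bg_tau <- stats::runif(n_bg, 0.25, 1.25)
  # under the null control the module genes follow the background model too
  if (null_control) {
    mod_level <- spec$baseline + stats::runif(n_mod, 0, 7)
    mod_tau <- stats::runif(n_mod, 0.25, 1.25)
  }

  experiments <- vector("list", length(spec$designs))
  for (k in seq_along(spec$designs)) {
    d <- spec$designs[[k]]
    g <- d$groups
    mids <- stage_midpoint(g$stage)
    reps <- as.integer(g$replicates)
    sample_group <- rep(seq_len(nrow(g)), reps)
    n_samples <- length(sample_group)
    sheet <- as_sample_sheet(data.frame(
      sample_id = sprintf("%s_s%02d", d$accession, seq_len(n_samples)),
      tissue = g$tissue[sample_group],
      stage = g$stage[sample_group],
      genotype = g$genotype[sample_group],
      replicate = stats::ave(seq_len(n_samples), sample_group,
                             FUN = seq_along),
      stringsAsFactors = FALSE))
    is_target <- g$tissue %in% target_tissues
    latent <- stats::rnorm(n_samples)  # shared per-sample module factor

    vals <- matrix(NA_real_, length(genes), n_samples,
                   dimnames = list(genes, sheet$sample_id))
    for (m in seq_len(n_mod)) {
      if (null_control) {
        gmean <- mod_level[m] + stats::rnorm(nrow(g), 0, mod_tau[m])
        vals[m, ] <- gmean[sample_group] +
          stats::rnorm(n_samples, 0, spec$noise_sd)
      } else {
        tmpl <- planted_template(mids)
        priv <- stats::runif(nrow(g)) * as.numeric(tmpl > 0 | is_target &
                                                     mids >= 1 & mids <= 10)
        profile <- spec$rho * tmpl + (1 - spec$rho) * priv
        gmean <- ifelse(is_target,
                        spec$baseline + amp[m] * profile,
                        spec$baseline + spec$leakage * amp[m])
        noise <- spec$noise_sd * (sqrt(spec$rho) * latent +
                                    sqrt(1 - spec$rho) *
                                    stats::rnorm(n_samples))
        vals[m, ] <- gmean[sample_group] + noise
      }
    }
    for (b in seq_along(bg_ids)) {
      gmean <- bg_level[b] + stats::rnorm(nrow(g), 0, bg_tau[b])
      vals[n_mod + b, ] <- gmean[sample_group] +
        stats::rnorm(n_samples, 0, spec$noise_sd)
    }
    experiments[[k]] <- expression_experiment(vals, d$accession,
                                              samples = sheet)
  }

  # expressed windows implied by the template: the 3-4 DAP peak plus the
  # early part of the 5-10 DAP decline
  truth <- data.frame(
    gene_id = module_ids,
    is_module = TRUE,
    is_bait = module_ids %in% bait_ids,
    exclusive = !null_control,
    peak_window = if (null_control) NA_character_ else "3-4 DAP",
    label = if (null_control) NA_character_ else
      "3-4 DAP, 5-10 DAP, endosperm",
    stringsAsFactors = FALSE
  )
  list(atlas = atlas(experiments), truth = truth)
}

#' Precision and recall of a candidate set against planted truth
#'
#' Precision is computed over all reported candidates; recall over the
#' recoverable module (module genes that are not baits, since baits are
#' excluded from candidacy by construction). An empty candidate set has
#' undefined precision (`NA`) and recall 0.
#'
#' @param candidates A [select_candidates()] result or character vector of
#'   gene ids.
#' @param truth Truth data frame from [make_atlas()].
#' @return List with `precision`, `recall`, `n_candidates`,
#'   `n_true_positive`.
#' @export
recovery_metrics <- function(candidates, truth) {
  ids <- if (inherits(candidates, "candidate_set"))
    candidate_genes(candidates) else as.character(candidates)
  module <- truth$gene_id[truth$is_module]
  recoverable <- truth$gene_id[truth$is_module & !truth$is_bait]
  tp <- length(intersect(ids, module))
  list(
    precision = if (length(ids) == 0L) NA_real_ else tp / length(ids),
    recall = if (length(recoverable) == 0L) NA_real_ else
      length(intersect(ids, recoverable)) / length(recoverable),
    n_candidates = length(ids),
    n_true_positive = tp
  )
}

#' Write a synthetic atlas to disk in the interchange formats
#'
#' One `<accession>_matrix.tsv` and `<accession>_samples.tsv` per
#' experiment, plus `truth.json` with the planted ground truth.
#'
#' @param sim Result of [make_atlas()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_atlas <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (e in sim$atlas$experiments) {
    mf <- file.path(dir, paste0(e$accession, "_matrix.tsv"))
    sf <- file.path(dir, paste0(e$accession, "_samples.tsv"))
    write_expression_matrix(e, mf)
    write_sample_sheet(e$samples, sf)
    files <- c(files, mf, sf)
  }
  tf <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, tf, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, tf))
}
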