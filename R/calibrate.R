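#' Configuration of the calibration pipeline
#'
#' The calibration pipeline mirrors how generated trees are compared to a
#' reference cohort: each seed tree is pruned to its coarse anatomy, leaf
#' targets are sampled (oversampled by `1/0.27`, because one bifurcation
#' level is pruned again afterwards), the tree is extended by CCO, the leaf
#' level is pruned, very short edges are contracted, optionally the angle
#' postprocessing is applied, and the generated population is scored
#' against the reference population.
#'
#' Defaults are desk-scale (leaf counts 30-80, 3 repetitions); the
#' full-scale study settings (150-350, 12 repetitions) are a matter of
#' raising `leaf_range` and `repetitions`.
#'
#' @param reference list of [vascular_tree()]: the reference population.
#' @param leaf_range range of desired (post-pruning) leaf counts.
#' @param repetitions generated trees per seed tree.
#' @param oversample leaf oversampling factor (default `1/0.27`).
#' @param min_distance minimal distance between leaf targets, mm.
#' @param contract_threshold short-edge contraction threshold, mm.
#' @param postprocess apply [bisector_shift()] + [nonflatness_adjust()]
#'   ("improved" generation) when `TRUE`.
#' @param bisector_fraction see [bisector_shift()].
#' @param nonflatness_dist a [nonflatness_distribution()] for the
#'   postprocessing.
#' @param prune_coarse,prune_leaves toggles for the pruning stages.
#' @param cco a [cco_config()].
#' @param similarity a [similarity_config()].
#' @param seed integer master seed (per-run seeds are derived from it).
#' @return a list of class `calibration_config`.
#' @export
calibration_config <- function(reference,
                               leaf_range = c(30, 80), repetitions = 3,
                               oversample = 1 / 0.27, min_distance = 1,
                               contract_threshold = 0.1,
                               postprocess = FALSE,
                               bisector_fraction = 0.09,
                               nonflatness_dist =
                                 synthetic_nonflatness_distribution(),
                               prune_coarse = TRUE, prune_leaves = TRUE,
                               cco = cco_config(),
                               similarity = similarity_config(),
                               seed = 1L) {
  stopifnot(is.list(reference), length(reference) >= 1)
  structure(as.list(environment()), class = "calibration_config")
}

#' Run the calibration pipeline
#'
#' Generates `repetitions` CCO trees per seed tree through the full
#' pipeline of [calibration_config()] and scores the generated population
#' against the reference population with [similarity_report()].
#'
#' @param seed_trees a [vascular_tree()] or list of them (the measured-tree
#'   stand-ins whose coarse anatomy is extended).
#' @param domain an [organ_domain].
#' @param config a [calibration_config()].
#' @return list of class `calibration_result`: `report` (the two-population
#'   [similarity_report()]), `generated` (list of trees), `details` (one
#'   record per run: seeds, target counts, leaf counts at each stage).
#' @export
calibration_run <- function(seed_trees, domain, config) {
  stopifnot(inherits(config, "calibration_config"))
  if (inherits(seed_trees, "vascular_tree")) seed_trees <- list(seed_trees)
  generated <- list()
  details <- list()
  run <- 0L
  for (i in seq_along(seed_trees)) {
    coarse <- if (config$prune_coarse)
      prune_to_coarse(seed_trees[[i]], domain) else seed_trees[[i]]
    for (rep in seq_len(config$repetitions)) {
      run <- run + 1L
      run_seed <- (config$seed * 1000L + run) %% .Machine$integer.max
      n_desired <- with_local_seed(run_seed * 2L + 1L, {
        sample(seq.int(config$leaf_range[1L], config$leaf_range[2L]), 1L)
      })
      n_targets <- ceiling(n_desired * config$oversample)
      targets <- sample_leaf_targets(domain, n_targets,
                                     min_distance = config$min_distance,
                                     seed = run_seed)
      tree <- generate_tree(coarse, domain, targets, config$cco)
      n_generated_leaves <- length(leaf_edges(tree))
      if (config$prune_leaves) tree <- prune_leaf_level(tree)
      tree <- contract_short_edges(tree, config$contract_threshold)
      if (config$postprocess) {
        tree <- bisector_shift(tree, config$bisector_fraction)
        tree <- nonflatness_adjust(tree, config$nonflatness_dist,
                                   seed = run_seed)
      }
      generated[[run]] <- tree
      details[[run]] <- data.frame(
        seed_tree = i, repetition = rep, run_seed = run_seed,
        n_desired = n_desired, n_targets = n_targets,
        leaves_generated = n_generated_leaves,
        leaves_final = length(leaf_edges(tree)))
    }
  }
  report <- similarity_report(config$reference, generated,
                              config$similarity)
  structure(list(report = report, generated = generated,
                 details = do.call(rbind, details)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration run:", length(x$generated), "generated trees\n")
  print(x$report)
  invisible(x)
}

#' Cost-exponent sweep
#'
#' Repeats the calibration pipeline for a sequence of cost exponents
#' \eqn{\lambda} and tabulates the group and total similarities, the usual
#' check that \eqn{\lambda = 2} (intravascular volume) gives the best
#' overall agreement.
#'
#' @param seed_trees,domain,config as in [calibration_run()].
#' @param lambdas numeric vector of cost exponents.
#' @return data frame with one row per lambda: `lambda`, `radius`,
#'   `length`, `angle`, `total`.
#' @export
lambda_sweep <- function(seed_trees, domain, config,
                         lambdas = seq(1.4, 2.6, by = 0.2)) {
  rows <- lapply(lambdas, function(lam) {
    cfg <- config
    cfg$cco$lambda <- lam
    res <- calibration_run(seed_trees, domain, cfg)
    data.frame(lambda = lam,
               radius = res$report$groups[["radius"]],
               length = res$report$groups[["length"]],
               angle = res$report$groups[["angle"]],
               total = res$report$total)
  })
  do.call(rbind, rows)
}
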