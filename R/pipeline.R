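#' Run the full analysis pipeline
#'
#' Orchestrates score -> bootstrap -> network -> metrics -> co-expression on
#' one dataset and returns a machine-readable run manifest.  Inputs are
#' either supplied directly (a [pulldown_matrix] with its control runs, a
#' role map, an expression matrix) or generated by the synthetic module via
#' `sim`.  Every default matches the study design the scoring scheme was
#' built for: triplicate pull-downs, 10,000 bootstrap resamples with pool
#' screening at R < 0.3, 100,000 role permutations.
#'
#' @param pulldowns a [pulldown_matrix] (with control runs), or `NULL` to
#'   simulate via `sim`
#' @param roles named role vector (optional; required for the agreement
#'   statistics)
#' @param expression gene x condition matrix (optional; required for the
#'   co-expression stage)
#' @param sim a [sim_config] used when `pulldowns` is `NULL`
#' @param out_dir if non-`NULL`, stage outputs (scores.tsv, pvals.tsv,
#'   network files, manifest.json) are written there
#' @param k_reps,sticky_threshold,median_missing,no_control scoring
#'   parameters, see [apms_score()]
#' @param n_boot,r_threshold bootstrap parameters, see [bootstrap_config()]
#' @param n_perm role-permutation count, see [permutation_test()]
#' @param alpha significance level for the "significant interactions" counts
#' @param seed integer seed for all stochastic stages
#' @param skip character vector of stage names to skip
#'   (`"bootstrap"`, `"network"`, `"coexpr"`)
#' @return list of class `run_manifest`; the full stage objects are attached
#'   as attribute `stages` (`fit`, `pvals`, `network`, `agreement_test`,
#'   `coexpression`, `truth` when simulated)
#' @export
run_pipeline <- function(pulldowns = NULL, roles = NULL, expression = NULL,
                         sim = NULL, out_dir = NULL, k_reps = 3L,
                         sticky_threshold = 0,
                         median_missing = "zero", no_control = FALSE,
                         n_boot = 10000L, r_threshold = 0.3,
                         n_perm = 100000L, alpha = 0.001, seed = 1L,
                         skip = character()) {
  truth <- NULL
  if (is.null(pulldowns)) {
    if (is.null(sim)) stop("supply either 'pulldowns' or 'sim'")
    sim$seed <- seed
    simdata <- simulate_pulldowns(sim)
    pulldowns <- simdata$pulldowns
    truth <- simdata$truth
    if (is.null(roles)) roles <- simdata$roles
    if (is.null(expression)) expression <- simdata$expression
    if (!pd_has_control(pulldowns)) no_control <- TRUE
  }
  stages <- list(truth = truth)

  fit <- apms_score(pulldowns, k_reps = k_reps,
                    sticky_threshold = sticky_threshold,
                    median_missing = median_missing,
                    no_control = no_control)
  stages$fit <- fit

  pvals <- NULL
  if (!"bootstrap" %in% skip) {
    pvals <- significance_table(pulldowns,
                                bootstrap_config(n_boot = n_boot,
                                                 r_threshold = r_threshold,
                                                 seed = seed))
    stages$pvals <- pvals
  }

  net <- agreement <- NULL
  profile_cor <- NULL
  if (!"network" %in% skip) {
    net <- build_network(fit, roles = roles, pvals = pvals)
    stages$network <- net
    profile_cor <- profile_correlations(fit)
    stages$profile_correlations <- profile_cor
    if (!is.null(roles) && nrow(net$edges) > 0) {
      agreement <- permutation_test(net, roles, n_perm = n_perm,
                                    seed = seed)
      stages$agreement_test <- agreement
    }
  }

  coexpr <- NULL
  if (!"coexpr" %in% skip && !is.null(expression) && !is.null(net) &&
      nrow(net$edges) > 0) {
    sets <- interaction_pair_sets(net, pd_proteins(pulldowns))
    coexpr <- tryCatch(
      compare_sets(sets$interacting, sets$noninteracting, expression),
      error = function(e) NULL)
    stages$coexpression <- coexpr
  }

  hc <- fit$confidence[fit$confidence$high_confidence &
                         fit$confidence$protein != fit$confidence$bait, ]
  deg <- if (!is.null(net)) degree_summary(net) else NULL
  rec <- if (!is.null(net)) reciprocal_rate(net) else NULL
  sig_edges <- sig_baits <- NA_integer_
  if (!is.null(pvals)) {
    hc_key <- paste(hc$bait, hc$protein, sep = "\r")
    p_key <- paste(pvals$bait, pvals$protein, sep = "\r")
    sig <- pvals[which(pvals$p_value < alpha), , drop = FALSE]
    sig_edges <- sum(paste(sig$bait, sig$protein, sep = "\r") %in% hc_key &
                       sig$bait != sig$protein)
    sig_baits <- sum(sig$bait == sig$protein)
  }
  manifest <- list(
    version = as.character(utils::packageVersion("apmsnet")),
    seed = as.integer(seed),
    params = list(k_reps = k_reps, sticky_threshold = sticky_threshold,
                  median_missing = median_missing, n_boot = n_boot,
                  r_threshold = r_threshold, n_perm = n_perm,
                  alpha = alpha),
    skipped = as.character(skip),
    n_baits = length(pd_baits(pulldowns)),
    n_proteins_observed = length(pd_proteins(pulldowns)),
    n_proteins_control = length(fit$baseline),
    n_proteins_adjusting = sum(fit$baseline > 0),
    n_high_confidence_edges = nrow(hc),
    n_prey = if (!is.null(deg)) deg$n_prey else length(unique(hc$protein)),
    mean_prey_per_bait = if (!is.null(deg)) deg$mean_prey_per_bait else NA,
    mean_baits_per_prey = if (!is.null(deg)) deg$mean_baits_per_prey else NA,
    n_significant_edges = sig_edges,
    n_significant_baits = sig_baits,
    reciprocal_observed = if (!is.null(rec)) rec$observed else NA,
    reciprocal_possible = if (!is.null(rec)) rec$possible else NA,
    reciprocal_rate = if (!is.null(rec)) rec$rate else NA,
    functional_agreement =
      if (!is.null(agreement)) agreement$observed_agreement else NA,
    permuted_agreement =
      if (!is.null(agreement)) agreement$permuted_mean else NA,
    agreement_p = if (!is.null(agreement)) agreement$p_value else NA,
    coexpr_mean_interacting =
      if (!is.null(coexpr)) coexpr$mean_interacting else NA,
    coexpr_mean_noninteracting =
      if (!is.null(coexpr)) coexpr$mean_noninteracting else NA,
    coexpr_p = if (!is.null(coexpr)) coexpr$p_value else NA)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(fit$confidence, file.path(out_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(pvals))
      utils::write.table(pvals, file.path(out_dir, "pvals.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(net)) {
      write_network(net, file.path(out_dir, "network.net"), "pajek_net")
      write_network(net, file.path(out_dir, "network.sif"), "sif")
      write_network(net, file.path(out_dir, "edges.tsv"), "edge_tsv")
    }
    files <- list.files(out_dir, full.names = TRUE)
    files <- files[!grepl("manifest\\.json$", files)]
    manifest$output_digests <- as.list(tools::md5sum(sort(files)))
    names(manifest$output_digests) <- basename(sort(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(manifest, class = "run_manifest", stages = stages)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("apmsnet run manifest (seed ", x$seed, ")\n", sep = "")
  cat("  high-confidence edges: ", x$n_high_confidence_edges, " over ",
      x$n_baits, " baits and ", x$n_prey, " prey\n", sep = "")
  if (!is.na(x$n_significant_edges))
    cat("  significant at p < ", x$params$alpha, ": ",
        x$n_significant_edges, " interactions, ", x$n_significant_baits,
        " baits\n", sep = "")
  if (!is.na(x$reciprocal_rate))
    cat("  reciprocal confirmation: ", x$reciprocal_observed, "/",
        x$reciprocal_possible, "\n", sep = "")
  if (!is.na(x$functional_agreement))
    cat(sprintf("  role agreement: %.3f observed vs %.3f permuted (p = %.3g)\n",
                x$functional_agreement, x$permuted_agreement,
                x$agreement_p))
  if (!is.na(x$coexpr_mean_interacting))
    cat(sprintf("  co-expression: %.2f interacting vs %.2f non-interacting (p = %.3g)\n",
                x$coexpr_mean_interacting, x$coexpr_mean_noninteracting,
                x$coexpr_p))
  invisible(x)
}

#' Read a pipeline run configuration file
#'
#' YAML (if the yaml package is installed) or JSON file whose top-level keys
#' are arguments of [run_pipeline()]; the `sim` key, when present, is passed
#' through [sim_config()].
#'
#' @param path config file path
#' @return named list of arguments for [run_pipeline()]
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$sim)) cfg$sim <- do.call(sim_config, cfg$sim)
  cfg
}
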