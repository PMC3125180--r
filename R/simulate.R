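#' Configuration for the synthetic pull-down generator
#'
#' Defaults emulate the study design the package targets: 12 baits pulled
#' down in biological triplicate, six elution fractions per run, a planted
#' complex of prey per bait drawn from a shared prey pool (so prey are
#' re-used across baits), a designated number of reciprocal bait pairs, a
#' sticky-protein background that elutes in every pull-down and in the
#' no-bait control, multiplicative log-normal abundance noise with dropout,
#' and gene-expression profiles in which co-complex genes load on a shared
#' latent factor.
#'
#' @param n_baits number of bait proteins
#' @param n_proteins protein universe size
#' @param n_replicates biological replicates per bait and for the control
#' @param n_fractions elution fractions per run
#' @param complex_size integer range (min, max) of planted prey per bait
#' @param prey_pool_size size of the shared prey pool complexes draw from
#' @param n_reciprocal_pairs bait pairs planted as mutual complex members
#'   (default 3, capped at half the baits)
#' @param n_sticky sticky background proteins (control-visible)
#' @param bait_empai_mean mean emPAI of a bait protein in its own pull-down
#' @param prey_ratio_range per-prey abundance as a fraction of the bait mean
#'   (uniform range)
#' @param sticky_empai_mean mean emPAI of sticky proteins in every run
#' @param noise_sigma sdlog of the multiplicative log-normal abundance noise
#' @param dropout probability that a planted protein is missing from one
#'   replicate entirely
#' @param peak_width Gaussian elution-peak width (in fractions); peak
#'   centers jitter by one fraction between replicates, which is what makes
#'   the max-over-fractions summary necessary
#' @param min_detect detection floor; fraction values below it are not
#'   reported (absence, not zero)
#' @param n_roles,role_fidelity,unannotated_rate functional-role labels:
#'   number of labels, probability a complex member inherits its complex's
#'   label, probability a protein is left unannotated
#' @param n_conditions,factor_loading expression profiles: number of
#'   conditions and latent-factor loading of co-complex genes
#' @param seed integer RNG seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_baits = 12L, n_proteins = 300L, n_replicates = 3L,
                       n_fractions = 6L, complex_size = c(6L, 12L),
                       prey_pool_size = 90L, n_reciprocal_pairs = NULL,
                       n_sticky = 30L, bait_empai_mean = 3,
                       prey_ratio_range = c(0.2, 0.8),
                       sticky_empai_mean = 1, noise_sigma = 0.5,
                       dropout = 0.05, peak_width = 1, min_detect = 0.01,
                       n_roles = 8L, role_fidelity = 0.7,
                       unannotated_rate = 0.2, n_conditions = 106L,
                       factor_loading = 0.8, seed = 1L) {
  if (is.null(n_reciprocal_pairs))
    n_reciprocal_pairs <- min(3L, floor(n_baits / 2))
  cfg <- as.list(environment())
  stopifnot(n_baits >= 1, n_proteins > n_baits + n_sticky,
            n_replicates >= 1, n_fractions >= 1,
            complex_size[1] <= complex_size[2],
            prey_pool_size >= complex_size[2],
            n_proteins - n_baits - n_sticky >= complex_size[2],
            n_reciprocal_pairs <= floor(n_baits / 2),
            dropout >= 0, dropout <= 1, noise_sigma >= 0,
            role_fidelity >= 0, role_fidelity <= 1,
            abs(factor_loading) <= 1)
  structure(cfg, class = "sim_config")
}

# size-safe sample: never triggers the scalar-n expansion of sample()
resample <- function(x, ...) x[sample.int(length(x), ...)]

# discretized Gaussian elution peak, max weight 1 (so the per-replicate
# maximum over fractions recovers the amplitude exactly when noiseless)
elution_weights <- function(n_fractions, center, width) {
  f <- seq_len(n_fractions)
  w <- exp(-(f - center)^2 / (2 * width^2))
  w / max(w)
}

#' Generate a synthetic pull-down study with planted ground truth
#'
#' Produces everything a pipeline run needs: an emPAI [pulldown_matrix]
#' including no-bait control replicates, the planted truth (directed
#' bait -> prey edges and the sticky set), functional-role labels, and a
#' gene x condition expression matrix.  Fully deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config]
#' @return list with elements `pulldowns`, `truth` (list: `edges`
#'   data.frame, `sticky`, `complexes`, `config`), `roles`, `expression`
#' @examples
#' sim <- simulate_pulldowns(sim_config(n_baits = 3, n_proteins = 50,
#'                                      seed = 42))
#' sim$pulldowns
#' head(sim$truth$edges)
#' @export
simulate_pulldowns <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  proteins <- sprintf("P%04d", seq_len(cfg$n_proteins))
  baits <- proteins[seq_len(cfg$n_baits)]
  rest <- setdiff(proteins, baits)
  sticky <- sort(sample(rest, cfg$n_sticky))
  avail <- setdiff(rest, sticky)
  pool <- resample(avail, min(cfg$prey_pool_size, length(avail)))

  # planted complexes: each bait draws prey from the shared pool
  complexes <- lapply(baits, function(b) {
    size <- resample(seq(cfg$complex_size[1], cfg$complex_size[2]), 1L)
    sort(resample(pool, size))
  })
  names(complexes) <- baits
  # reciprocal bait pairs: mutual membership
  if (cfg$n_reciprocal_pairs > 0) {
    pair_baits <- matrix(sample(baits, 2L * cfg$n_reciprocal_pairs),
                         ncol = 2L)
    for (i in seq_len(nrow(pair_baits))) {
      a <- pair_baits[i, 1]; b <- pair_baits[i, 2]
      complexes[[a]] <- sort(unique(c(complexes[[a]], b)))
      complexes[[b]] <- sort(unique(c(complexes[[b]], a)))
    }
  }

  # fixed per-protein abundance parameters
  prey_ratio <- stats::setNames(
    stats::runif(length(proteins), cfg$prey_ratio_range[1],
                 cfg$prey_ratio_range[2]), proteins)
  sticky_mean <- stats::setNames(
    cfg$sticky_empai_mean *
      exp(stats::rnorm(length(sticky), 0, cfg$noise_sigma)), sticky)
  complex_center <- stats::setNames(
    resample(seq(2L, max(2L, cfg$n_fractions - 1L)), cfg$n_baits,
             replace = TRUE), baits)
  sticky_center <- stats::setNames(
    resample(seq_len(cfg$n_fractions), length(sticky), replace = TRUE),
    sticky)

  noise <- function(n) exp(stats::rnorm(n, 0, cfg$noise_sigma))
  rows <- list()
  emit <- function(protein, bait, rep, amplitude, center) {
    w <- elution_weights(cfg$n_fractions, center, cfg$peak_width)
    vals <- amplitude * w
    keep <- vals >= cfg$min_detect
    if (!any(keep)) return(NULL)
    data.frame(protein = protein, bait = bait, replicate = rep,
               fraction = which(keep), empai = vals[keep],
               stringsAsFactors = FALSE)
  }
  jitter1 <- function(center)
    min(max(center + sample(-1:1, 1L), 1L), cfg$n_fractions)

  for (b in baits) {
    members <- c(b, complexes[[b]])
    amp_mean <- ifelse(members == b, cfg$bait_empai_mean,
                       cfg$bait_empai_mean * prey_ratio[members])
    for (r in seq_len(cfg$n_replicates)) {
      center <- jitter1(complex_center[b])
      dropped <- stats::runif(length(members)) < cfg$dropout
      for (i in seq_along(members)) {
        if (dropped[i]) next
        rows[[length(rows) + 1L]] <-
          emit(members[i], b, r, amp_mean[i] * noise(1L), center)
      }
      # sticky background rides along in every pull-down
      s_drop <- stats::runif(length(sticky)) < cfg$dropout
      for (s in sticky[!s_drop]) {
        rows[[length(rows) + 1L]] <-
          emit(s, b, r, sticky_mean[s] * noise(1L),
               jitter1(sticky_center[s]))
      }
    }
  }
  for (r in seq_len(cfg$n_replicates)) {
    s_drop <- stats::runif(length(sticky)) < cfg$dropout
    for (s in sticky[!s_drop]) {
      rows[[length(rows) + 1L]] <-
        emit(s, CONTROL_ID, r, sticky_mean[s] * noise(1L),
             jitter1(sticky_center[s]))
    }
  }
  pulldowns <- pulldown_matrix(do.call(rbind, rows), baits = baits)

  # truth edges: planted complex membership, directed bait -> prey
  truth_edges <- do.call(rbind, lapply(baits, function(b)
    if (length(complexes[[b]]))
      data.frame(bait = b, prey = complexes[[b]], stringsAsFactors = FALSE)))
  if (is.null(truth_edges))
    truth_edges <- data.frame(bait = character(), prey = character())

  # functional roles
  role_labels <- sprintf("role%02d", seq_len(cfg$n_roles))
  complex_role <- stats::setNames(
    sample(role_labels, cfg$n_baits, replace = TRUE), baits)
  roles <- stats::setNames(sample(role_labels, cfg$n_proteins,
                                  replace = TRUE), proteins)
  for (b in baits) {
    members <- c(b, complexes[[b]])
    inherit <- stats::runif(length(members)) < cfg$role_fidelity
    roles[members[inherit]] <- complex_role[b]
  }
  drop_ann <- stats::runif(cfg$n_proteins) < cfg$unannotated_rate
  roles <- roles[!drop_ann]

  # expression: co-complex genes share a latent factor
  expr <- matrix(stats::rnorm(cfg$n_proteins * cfg$n_conditions),
                 nrow = cfg$n_proteins,
                 dimnames = list(proteins,
                                 sprintf("cond%03d", seq_len(cfg$n_conditions))))
  lam <- cfg$factor_loading
  for (b in baits) {
    f <- stats::rnorm(cfg$n_conditions)
    members <- c(b, complexes[[b]])
    for (p in members)
      expr[p, ] <- lam * f + sqrt(1 - lam^2) * stats::rnorm(cfg$n_conditions)
  }

  list(pulldowns = pulldowns,
       truth = list(edges = truth_edges, sticky = sticky,
                    complexes = complexes, config = cfg),
       roles = roles,
       expression = expr)
}

#' Score a predicted network against planted truth
#'
#' Standard set-overlap metrics on directed bait -> prey edges, plus the
#' sticky contamination rate: the fraction of predicted edges whose prey is
#' a sticky background protein and which are not planted interactions.
#'
#' @param network an `interaction_network` (or a data.frame with `bait`,
#'   `prey` columns)
#' @param truth the `truth` element of [simulate_pulldowns()] output
#' @return list `(precision, recall, f1, contamination)`; precision is `NA`
#'   for an empty prediction
#' @export
evaluate_recovery <- function(network, truth) {
  pred <- if (inherits(network, "interaction_network")) network$edges
          else network
  pkey <- paste(pred$bait, pred$prey, sep = "\r")
  tkey <- paste(truth$edges$bait, truth$edges$prey, sep = "\r")
  tp <- sum(pkey %in% tkey)
  precision <- if (length(pkey)) tp / length(pkey) else NA_real_
  recall <- if (length(tkey)) tp / length(tkey) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  contamination <- if (length(pkey))
    sum(pred$prey %in% truth$sticky & !pkey %in% tkey) / length(pkey)
  else NA_real_
  list(precision = precision, recall = recall, f1 = f1,
       contamination = contamination)
}
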