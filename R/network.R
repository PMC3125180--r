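#' Build the high-confidence interaction network
#'
#' Assembles directed bait -> prey edges from the high-confidence rows of a
#' scored confidence table.  Self-edges (a bait pulling itself down) are
#' excluded from the edge set, but every bait is always present as a node;
#' an edge (A, B) between two baits is flagged reciprocal iff (B, A) is also
#' present.
#'
#' @param fit an `apms_fit` from [apms_score()], or its `confidence` table
#' @param roles optional named character vector of functional-role labels
#'   (e.g. TIGR roles) as from [read_roles()]
#' @param pvals optional [significance_table()] result; p-values are joined
#'   onto the edges
#' @return object of class `interaction_network`: list with `nodes`
#'   (protein, role, is_bait, bait_prominence) and `edges` (bait, prey,
#'   score, dashed, reciprocal, p_value)
#' @export
build_network <- function(fit, roles = NULL, pvals = NULL) {
  conf <- if (inherits(fit, "apms_fit")) fit$confidence else fit
  baits <- unique(conf$bait)
  hc <- conf[conf$high_confidence & conf$protein != conf$bait, , drop = FALSE]
  edges <- data.frame(bait = hc$bait, prey = hc$protein,
                      score = hc$score, dashed = hc$dashed,
                      stringsAsFactors = FALSE)
  ekey <- paste(edges$bait, edges$prey, sep = "\r")
  rkey <- paste(edges$prey, edges$bait, sep = "\r")
  edges$reciprocal <- rkey %in% ekey
  edges$p_value <- if (!is.null(pvals)) {
    pvals$p_value[match(ekey, paste(pvals$bait, pvals$protein, sep = "\r"))]
  } else rep(NA_real_, nrow(edges))
  proteins <- sort(unique(c(baits, edges$bait, edges$prey)))
  self <- conf[conf$protein == conf$bait, , drop = FALSE]
  prominence <- stats::setNames(rep(0, length(proteins)), proteins)
  if (nrow(self) && "score" %in% names(self))
    prominence[self$bait] <- self$score
  nodes <- data.frame(
    protein = proteins,
    role = if (is.null(roles)) NA_character_
           else as.character(roles[proteins]),
    is_bait = proteins %in% baits,
    bait_prominence = as.numeric(prominence[proteins]),
    stringsAsFactors = FALSE)
  o <- order(edges$bait, edges$prey)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  d <- degree_summary(x)
  cat("interaction_network: ", d$n_edges, " bait->prey edges, ",
      d$n_baits, " baits, ", d$n_prey, " prey (",
      sum(x$edges$reciprocal) / 2, " reciprocal pairs, ",
      sum(x$edges$dashed), " dashed edges)\n", sep = "")
  invisible(x)
}

#' Reciprocal-confirmation rate
#'
#' Internal-consistency statistic over bait pairs: for unordered pairs
#' \{A, B\} of distinct baits, a reciprocal interaction was *possible* if at
#' least one of the directed edges A->B, B->A was observed, and *observed*
#' if both were.  The rate is observed / possible.
#'
#' @param network an `interaction_network`
#' @param bait_set bait ids to consider (default: the network's bait nodes)
#' @return list `(observed, possible, rate)`; `rate` is `NA` when no
#'   bait-bait edge exists
#' @export
reciprocal_rate <- function(network,
                            bait_set = network$nodes$protein[network$nodes$is_bait]) {
  e <- network$edges
  bb <- e[e$bait %in% bait_set & e$prey %in% bait_set &
            e$bait != e$prey, , drop = FALSE]
  if (nrow(bb) == 0L)
    return(list(observed = 0L, possible = 0L, rate = NA_real_))
  pair <- ifelse(bb$bait < bb$prey,
                 paste(bb$bait, bb$prey, sep = "\r"),
                 paste(bb$prey, bb$bait, sep = "\r"))
  n_dir <- table(pair)
  possible <- length(n_dir)
  observed <- sum(n_dir == 2L)
  list(observed = observed, possible = possible,
       rate = observed / possible)
}

edge_agreement <- function(network, roles, drop_unannotated = FALSE) {
  e <- network$edges
  ra <- as.character(roles[e$bait])
  rb <- as.character(roles[e$prey])
  agree <- !is.na(ra) & !is.na(rb) & ra == rb
  if (drop_unannotated) {
    keep <- !is.na(ra) & !is.na(rb)
    if (!any(keep)) return(NA_real_)
    mean(agree[keep])
  } else {
    mean(agree)
  }
}

#' Functional-role agreement of a network
#'
#' Fraction of edges whose two endpoints share a functional-role label.
#' By default edges with an unannotated endpoint stay in the denominator and
#' never agree (role classifications are incomplete and this is the
#' conservative choice); `drop_unannotated = TRUE` removes them instead.
#'
#' @param network an `interaction_network`
#' @param roles named character vector protein -> role label
#' @param drop_unannotated drop edges with unannotated endpoints from the
#'   denominator
#' @return fraction in \[0, 1\]
#' @export
functional_agreement <- function(network, roles, drop_unannotated = FALSE) {
  if (nrow(network$edges) == 0L) return(NA_real_)
  edge_agreement(network, roles, drop_unannotated)
}

#' Permutation test for functional-role agreement
#'
#' Permutes the role labels across the proteins appearing in the network
#' (label multiset preserved) and recomputes the agreement each time; the
#' p-value is the fraction of permutations whose agreement reaches or
#' exceeds the observed one (ties count toward the null, so a degenerate
#' network in which every labeling agrees equally yields p = 1).
#'
#' @inheritParams functional_agreement
#' @param n_perm number of permutations
#' @param seed integer RNG seed
#' @return list of class `agreement_result` with `observed_agreement`,
#'   `permuted_mean`, `p_value`, `n_perm`
#' @export
permutation_test <- function(network, roles, n_perm = 100000L, seed = 1L,
                             drop_unannotated = FALSE) {
  if (nrow(network$edges) == 0L) stop("network has no edges")
  prot <- network$nodes$protein
  labels <- as.character(roles[prot])
  i1 <- match(network$edges$bait, prot)
  i2 <- match(network$edges$prey, prot)
  agree_frac <- function(lab) {
    a <- lab[i1]; b <- lab[i2]
    hit <- !is.na(a) & !is.na(b) & a == b
    if (drop_unannotated) {
      keep <- !is.na(a) & !is.na(b)
      if (!any(keep)) return(NA_real_)
      mean(hit[keep])
    } else mean(hit)
  }
  observed <- agree_frac(labels)
  set.seed(seed)
  perm_vals <- numeric(n_perm)
  n <- length(labels)
  for (k in seq_len(n_perm))
    perm_vals[k] <- agree_frac(labels[sample.int(n)])
  structure(list(observed_agreement = observed,
                 permuted_mean = mean(perm_vals, na.rm = TRUE),
                 p_value = sum(perm_vals >= observed, na.rm = TRUE) / n_perm,
                 n_perm = as.integer(n_perm)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(paste0("functional-role agreement: observed %.3f, ",
                     "permuted mean %.3f, p = %.4g (%d permutations)\n"),
              x$observed_agreement, x$permuted_mean, x$p_value, x$n_perm))
  invisible(x)
}

#' Bait-bait (and bait-control) prey-profile correlations
#'
#' Pearson correlations between bait pull-down profiles: each bait is the
#' vector of pseudo-confidence scores of the proteins observed in its
#' pull-downs, the control is its vector of median-max emPAI values, all
#' aligned on the union of observed proteins with 0 for unobserved.  A high
#' bait-control correlation flags a bait that itself binds the column.
#'
#' @param fit an `apms_fit`
#' @return symmetric correlation matrix over baits (plus the control when
#'   present), unit diagonal; `NA` where a profile is constant
#' @export
profile_correlations <- function(fit) {
  stopifnot(inherits(fit, "apms_fit"))
  conf <- fit$confidence
  baits <- pd_baits(fit$pulldowns)
  proteins <- sort(unique(conf$protein))
  cols <- lapply(baits, function(b) {
    v <- stats::setNames(rep(0, length(proteins)), proteins)
    sub <- conf[conf$bait == b, , drop = FALSE]
    v[sub$protein] <- sub$score
    v
  })
  ids <- baits
  if (length(fit$baseline)) {
    v <- stats::setNames(rep(0, length(proteins)), proteins)
    hit <- intersect(names(fit$baseline), proteins)
    v[hit] <- fit$baseline[hit]
    cols <- c(cols, list(v))
    ids <- c(ids, pd_control_id(fit$pulldowns))
  }
  m <- do.call(cbind, cols)
  colnames(m) <- ids
  sds <- apply(m, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(m))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- 1
  r
}

#' Degree summary of an interaction network
#'
#' @param network an `interaction_network`
#' @return list `(n_baits, n_edges, n_prey, mean_prey_per_bait,
#'   mean_baits_per_prey)`; means are rounded to 1 decimal.  Prey are all
#'   edge targets, including baits pulled down by other baits.
#' @export
degree_summary <- function(network) {
  baits <- network$nodes$protein[network$nodes$is_bait]
  e <- network$edges
  n_prey <- length(unique(e$prey))
  n_baits <- length(baits)
  list(n_baits = n_baits,
       n_prey = n_prey,
       n_edges = nrow(e),
       mean_prey_per_bait = if (n_baits) round(nrow(e) / n_baits, 1) else NA_real_,
       mean_baits_per_prey = if (n_prey) round(nrow(e) / n_prey, 1) else NA_real_)
}
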