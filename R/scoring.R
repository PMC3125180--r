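#' Per-replicate maximum emPAI over elution fractions
#'
#' The first step of the median-max summary: for one bait pull-down
#' biological replicate, each protein is summarized by its maximum emPAI
#' over all elution fractions in which it was observed.  The maximum (rather
#' than a fixed fraction) absorbs elution-profile shifts between replicates:
#' the same fraction number can represent different parts of the elution
#' profile in different runs.
#'
#' @param x a [pulldown_matrix]
#' @param bait_id bait (or control) id present in `x`
#' @param replicate_id replicate number present for that bait
#' @return named numeric vector over the proteins observed in >= 1 fraction
#'   of that run; unobserved proteins are absent, never 0.
#' @export
max_over_fractions <- function(x, bait_id, replicate_id) {
  if (!bait_id %in% x$bait)
    stop("unknown bait id: ", bait_id)
  sub <- x[x$bait == bait_id & x$replicate == replicate_id, , drop = FALSE]
  if (nrow(sub) == 0L && !replicate_id %in% pd_replicates(x, bait_id))
    stop("unknown replicate ", replicate_id, " for bait ", bait_id)
  if (nrow(sub) == 0L) return(stats::setNames(numeric(0), character(0)))
  v <- tapply(sub$empai, sub$protein, max)
  stats::setNames(as.numeric(v), names(v))
}

# per-replicate maxima for one bait as a proteins x replicates matrix,
# NA = protein not observed in that replicate
rep_max_matrix <- function(x, bait_id, replicates = NULL) {
  if (is.null(replicates)) replicates <- pd_replicates(x, bait_id)
  per_rep <- lapply(replicates, function(r) max_over_fractions(x, bait_id, r))
  proteins <- sort(unique(unlist(lapply(per_rep, names))))
  m <- matrix(NA_real_, nrow = length(proteins), ncol = length(replicates),
              dimnames = list(proteins, paste0("r", replicates)))
  for (j in seq_along(per_rep))
    m[names(per_rep[[j]]), j] <- per_rep[[j]]
  m
}

median_with_policy <- function(v, policy = c("zero", "drop")) {
  policy <- match.arg(policy)
  if (policy == "zero") v[is.na(v)] <- 0 else v <- v[!is.na(v)]
  if (length(v) == 0L) return(0)
  stats::median(v)
}

#' Control baseline: median of per-replicate maxima in the no-bait control
#'
#' For each protein seen in the no-bait control, the per-control-replicate
#' maxima over fractions are medianed across all control replicate slots.
#' Under the default `median_missing = "zero"` policy a replicate in which
#' the protein was not observed contributes 0, so a protein seen in only one
#' of three control replicates has baseline `median(x, 0, 0) = 0`; this is
#' the conservative reading of using all control observations regardless of
#' how many replicates they appeared in.
#'
#' @param x a [pulldown_matrix] containing control runs
#' @param median_missing `"zero"` (positional median, absent replicates count
#'   as 0) or `"drop"` (median over observed replicates only)
#' @param no_control if `TRUE`, an absent control yields an empty baseline
#'   (every protein gets 0) instead of an error.
#' @return named numeric vector over control-observed proteins; use
#'   [baseline_for()] to expand to any protein set (absent proteins get 0).
#' @export
control_baseline <- function(x, median_missing = c("zero", "drop"),
                             no_control = FALSE) {
  median_missing <- match.arg(median_missing)
  if (!pd_has_control(x)) {
    if (no_control) return(stats::setNames(numeric(0), character(0)))
    stop("no control replicates under bait id '", pd_control_id(x),
         "' (use no_control = TRUE to score without a control)")
  }
  m <- rep_max_matrix(x, pd_control_id(x))
  apply(m, 1L, median_with_policy, policy = median_missing)
}

#' Expand a control baseline to a protein set
#' @param baseline named vector from [control_baseline()]
#' @param proteins character vector of protein ids
#' @return numeric vector aligned to `proteins`, 0 where never seen in control
#' @export
baseline_for <- function(baseline, proteins) {
  out <- stats::setNames(rep(0, length(proteins)), proteins)
  hit <- intersect(proteins, names(baseline))
  out[hit] <- baseline[hit]
  out
}

#' Median-max emPAI table for one bait
#'
#' Per protein observed in a bait's pull-downs: per-replicate maxima over
#' fractions (absent replicate = 0 before adjustment), control-baseline
#' subtraction floored at 0, and the median across the replicate slots --
#' the "median-max emPAI value".  Both the adjusted and the unadjusted
#' median-max are reported: the high-confidence comparison against the
#' control is made on unadjusted values (comparing post-subtraction values
#' to the baseline would count the control twice).
#'
#' @param x a [pulldown_matrix]
#' @param bait_id bait id
#' @param baseline named control baseline from [control_baseline()]
#' @param k_reps expected replicate count; defaults to the replicates present
#' @param median_missing median policy for absent replicates, see
#'   [control_baseline()]
#' @return data.frame with columns `bait`, `protein`, `n_reps_present`,
#'   `control_baseline`, `median_max_raw`, `median_max` (adjusted); the
#'   per-replicate maxima matrix is attached as attribute `rep_max`.
#' @export
median_max <- function(x, bait_id, baseline, k_reps = NULL,
                       median_missing = c("zero", "drop")) {
  median_missing <- match.arg(median_missing)
  reps <- pd_replicates(x, bait_id)
  if (!length(reps)) stop("bait '", bait_id, "' has no replicates")
  if (!is.null(k_reps) && length(reps) != k_reps)
    stop("bait '", bait_id, "' has ", length(reps),
         " replicates, expected ", k_reps)
  m <- rep_max_matrix(x, bait_id, reps)
  proteins <- rownames(m)
  base <- baseline_for(baseline, proteins)
  raw <- m
  raw[is.na(raw)] <- if (median_missing == "zero") 0 else NA_real_
  adj <- pmax(sweep(raw, 1L, base, `-`), 0)
  mm_raw <- apply(raw, 1L, function(v) median_with_policy(v, median_missing))
  mm_adj <- apply(adj, 1L, function(v) median_with_policy(v, median_missing))
  out <- data.frame(bait = rep(bait_id, length(proteins)),
                    protein = proteins,
                    n_reps_present = as.integer(rowSums(!is.na(m))),
                    control_baseline = as.numeric(base),
                    median_max_raw = as.numeric(mm_raw),
                    median_max = as.numeric(mm_adj),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "rep_max") <- m
  out
}

#' Pseudo-confidence scores for one bait's median-max table
#'
#' Adjusted median-max values of all prey in a bait pull-down are divided by
#' the bait protein's own adjusted median-max; if the bait protein was not
#' observed (or its adjusted value is 0), the maximum prey value is used as
#' the normalizer instead.  An observed bait therefore scores exactly 1.
#'
#' @param mm a one-bait table from [median_max()]
#' @param bait_protein_id protein id of the bait protein (defaults to the
#'   bait id itself)
#' @return `mm` with columns `score` and `normalizer_source`
#'   (`"bait_median_max"` or `"max_prey"`) appended
#' @export
pseudo_confidence <- function(mm, bait_protein_id = mm$bait[1]) {
  if (nrow(mm) == 0L) return(cbind(mm, score = numeric(0),
                                   normalizer_source = character(0)))
  bait_val <- mm$median_max[mm$protein == bait_protein_id]
  if (length(bait_val) == 1L && bait_val > 0) {
    normalizer <- bait_val
    src <- "bait_median_max"
  } else {
    normalizer <- max(mm$median_max)
    src <- "max_prey"
  }
  if (normalizer <= 0) {
    warning("all median-max values are 0 for bait '", mm$bait[1],
            "': no scores")
    mm <- mm[0, , drop = FALSE]
    normalizer <- NA_real_
  }
  mm$score <- mm$median_max / normalizer
  mm$normalizer_source <- rep(src, nrow(mm))
  mm
}

# proteins present in every control replicate (used by the sticky-bait rule)
control_full_presence <- function(x) {
  if (!pd_has_control(x)) return(character(0))
  m <- rep_max_matrix(x, pd_control_id(x))
  rownames(m)[rowSums(!is.na(m)) == ncol(m)]
}

#' High-confidence interaction filter over all baits
#'
#' Applies the triplicate high-confidence rule to every bait: a (bait, prey)
#' pair is kept iff the prey was observed in all `k_reps` biological
#' replicates of that bait pull-down with a non-zero unadjusted median-max
#' emPAI value strictly greater than the control baseline for that protein.
#' Equality with a non-zero baseline is kept only under the sticky-bait
#' rule -- the bait protein itself is control-prominent (its own control
#' median-max exceeds `sticky_threshold`) and the prey was present in all
#' control replicates -- and such edges are flagged `dashed` (they carry no
#' abundance evidence beyond the control, so their score is nominal).
#'
#' @param x a [pulldown_matrix] with control runs (unless `no_control`)
#' @param k_reps required replicate count per bait (default 3)
#' @param sticky_threshold control median-max of the bait protein above which
#'   the sticky-bait equality rule is enabled (default 0)
#' @param median_missing see [control_baseline()]
#' @param no_control score without control subtraction (baseline 0 for all)
#' @return data.frame (one row per observed bait/protein pair) with the
#'   [median_max()] columns plus `score`, `normalizer_source`,
#'   `high_confidence` and `dashed`
#' @export
high_confidence_filter <- function(x, k_reps = 3L, sticky_threshold = 0,
                                   median_missing = c("zero", "drop"),
                                   no_control = FALSE) {
  median_missing <- match.arg(median_missing)
  baseline <- control_baseline(x, median_missing, no_control = no_control)
  ctrl_full <- control_full_presence(x)
  tabs <- lapply(pd_baits(x), function(b) {
    mm <- median_max(x, b, baseline, k_reps = k_reps,
                     median_missing = median_missing)
    pseudo_confidence(mm, bait_protein_id = b)
  })
  tab <- do.call(rbind, tabs)
  if (is.null(tab) || nrow(tab) == 0L)
    stop("no scored entries: matrix holds no bait pull-downs")
  bait_prom <- baseline_for(baseline, pd_baits(x)) > sticky_threshold
  sticky_ok <- bait_prom[tab$bait] & tab$protein %in% ctrl_full
  eq <- tab$median_max_raw == tab$control_baseline & tab$control_baseline > 0
  tab$dashed <- eq & sticky_ok
  tab$high_confidence <- tab$n_reps_present == k_reps &
    tab$median_max_raw > 0 &
    (tab$median_max_raw > tab$control_baseline | tab$dashed)
  tab$dashed <- tab$dashed & tab$high_confidence
  rownames(tab) <- NULL
  tab
}

#' Replicate agreement per bait
#'
#' Mean pairwise overlap of the prey sets observed in a bait's biological
#' replicates, before and after control subtraction (a protein counts as
#' present post-adjustment if its replicate maximum exceeds its control
#' baseline).  The default overlap is the Jaccard index; `"min"` divides the
#' intersection by the smaller replicate set instead.
#'
#' @param x a [pulldown_matrix]
#' @param denominator `"jaccard"` or `"min"`
#' @param median_missing see [control_baseline()]
#' @param no_control score without a control
#' @return data.frame with columns `bait`, `agreement_raw`,
#'   `agreement_adjusted` (control included as a bait row, its adjusted
#'   agreement is 0 by construction)
#' @export
replicate_agreement <- function(x, denominator = c("jaccard", "min"),
                                median_missing = c("zero", "drop"),
                                no_control = FALSE) {
  denominator <- match.arg(denominator)
  baseline <- control_baseline(x, match.arg(median_missing),
                               no_control = no_control)
  overlap <- function(a, b) {
    if (length(a) == 0L && length(b) == 0L) return(NA_real_)
    den <- switch(denominator,
                  jaccard = length(union(a, b)),
                  min = min(length(a), length(b)))
    if (den == 0L) return(NA_real_)
    length(intersect(a, b)) / den
  }
  ids <- c(pd_baits(x), if (pd_has_control(x)) pd_control_id(x))
  rows <- lapply(ids, function(b) {
    reps <- pd_replicates(x, b)
    if (length(reps) < 2L)
      return(data.frame(bait = b, agreement_raw = NA_real_,
                        agreement_adjusted = NA_real_))
    sets_raw <- lapply(reps, function(r) names(max_over_fractions(x, b, r)))
    sets_adj <- lapply(reps, function(r) {
      v <- max_over_fractions(x, b, r)
      names(v)[v - baseline_for(baseline, names(v)) > 0]
    })
    pairs <- utils::combn(length(reps), 2L)
    mean_over <- function(sets) {
      vals <- apply(pairs, 2L, function(ij)
        overlap(sets[[ij[1]]], sets[[ij[2]]]))
      mean(vals, na.rm = FALSE)
    }
    data.frame(bait = b, agreement_raw = mean_over(sets_raw),
               agreement_adjusted = mean_over(sets_adj))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the pull-down confidence model
#'
#' The main entry point of the package: takes a replicated emPAI pull-down
#' matrix with its no-bait control and computes the full confidence scoring
#' -- control baseline, per-bait median-max tables, pseudo-confidence
#' scores, the high-confidence interaction filter and replicate agreement.
#' The result feeds [significance_table()], [build_network()] and the
#' validation statistics.
#'
#' @inheritParams high_confidence_filter
#' @param agreement_denominator see [replicate_agreement()]
#' @return an object of class `apms_fit` with elements `pulldowns`,
#'   `baseline`, `confidence` (the scored table), `agreement` and `params`
#' @examples
#' sim <- simulate_pulldowns(sim_config(n_baits = 3, n_proteins = 80,
#'                                      seed = 1))
#' fit <- apms_score(sim$pulldowns)
#' fit
#' head(subset(fit$confidence, high_confidence))
#' @export
apms_score <- function(x, k_reps = 3L, sticky_threshold = 0,
                       median_missing = c("zero", "drop"),
                       no_control = FALSE,
                       agreement_denominator = c("jaccard", "min")) {
  median_missing <- match.arg(median_missing)
  agreement_denominator <- match.arg(agreement_denominator)
  stopifnot(inherits(x, "pulldown_matrix"))
  conf <- high_confidence_filter(x, k_reps = k_reps,
                                 sticky_threshold = sticky_threshold,
                                 median_missing = median_missing,
                                 no_control = no_control)
  structure(list(
    pulldowns = x,
    baseline = control_baseline(x, median_missing, no_control = no_control),
    confidence = conf,
    agreement = replicate_agreement(x, agreement_denominator,
                                    median_missing, no_control = no_control),
    params = list(k_reps = k_reps, sticky_threshold = sticky_threshold,
                  median_missing = median_missing, no_control = no_control,
                  agreement_denominator = agreement_denominator)),
    class = "apms_fit")
}

#' @export
print.apms_fit <- function(x, ...) {
  hc <- x$confidence[x$confidence$high_confidence, , drop = FALSE]
  hc <- hc[hc$protein != hc$bait, , drop = FALSE]
  cat("apms_fit: pseudo-confidence scoring of ",
      length(pd_baits(x$pulldowns)), " bait pull-downs\n", sep = "")
  cat("  proteins scored:        ", nrow(x$confidence), " (bait, protein) pairs\n",
      sep = "")
  cat("  control baseline:       ", length(x$baseline),
      " proteins seen in no-bait control\n", sep = "")
  cat("  high-confidence edges:  ", nrow(hc), " (self-edges excluded, ",
      sum(hc$dashed), " dashed)\n", sep = "")
  invisible(x)
}

#' @export
summary.apms_fit <- function(object, ...) {
  hc <- object$confidence[object$confidence$high_confidence, , drop = FALSE]
  hc <- hc[hc$protein != hc$bait, , drop = FALSE]
  per_bait <- table(factor(hc$bait, levels = pd_baits(object$pulldowns)))
  out <- list(n_baits = length(pd_baits(object$pulldowns)),
              n_edges = nrow(hc),
              n_prey = length(unique(hc$protein)),
              edges_per_bait = per_bait,
              agreement = object$agreement,
              params = object$params)
  class(out) <- "summary.apms_fit"
  out
}

#' @export
print.summary.apms_fit <- function(x, ...) {
  cat("High-confidence network: ", x$n_edges, " bait->prey edges, ",
      x$n_baits, " baits, ", x$n_prey, " prey proteins\n", sep = "")
  cat("Edges per bait:\n")
  print(x$edges_per_bait)
  cat("Replicate agreement (", x$params$agreement_denominator, "):\n",
      sep = "")
  print(x$agreement, digits = 3)
  invisible(x)
}

#' Pseudo-confidence scores of a fit
#' @param object an `apms_fit`
#' @param ... unused
#' @return named numeric vector of high-confidence edge scores, names
#'   `"bait->prey"`
#' @export
coef.apms_fit <- function(object, ...) {
  hc <- object$confidence[object$confidence$high_confidence, , drop = FALSE]
  hc <- hc[hc$protein != hc$bait, , drop = FALSE]
  stats::setNames(hc$score, paste0(hc$bait, "->", hc$protein))
}

#' Plot a pull-down confidence fit
#'
#' Histogram of pseudo-confidence scores with the high-confidence subset
#' overlaid.
#' @param x an `apms_fit`
#' @param ... passed to [graphics::hist()]
#' @export
plot.apms_fit <- function(x, ...) {
  sc <- x$confidence$score
  graphics::hist(sc, breaks = 30, col = "grey85", border = "white",
                 main = "Pseudo-confidence scores",
                 xlab = "score (bait-normalized adjusted median-max emPAI)",
                 ...)
  hc <- x$confidence$score[x$confidence$high_confidence]
  graphics::hist(hc, breaks = 30, col = "steelblue", border = "white",
                 add = TRUE)
  graphics::legend("topright", fill = c("grey85", "steelblue"),
                   legend = c("all scored pairs", "high confidence"),
                   bty = "n")
  invisible(x)
}
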