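#' Percentile rank of transcript abundance
#'
#' Converts each gene's mean log2 expression ratio (across conditions,
#' missing values dropped) to a percentile rank among all genes, with the
#' highest percentile (100) corresponding to the maximum observed
#' expression.  Ties share their average rank; the convention is
#' `rank / n * 100`.
#'
#' @param expression gene x condition matrix of normalized log2 ratios as
#'   from [read_expression()]
#' @return named numeric vector of ranks in (0, 100]; genes whose values are
#'   all missing are excluded with a warning
#' @export
percentile_rank <- function(expression) {
  if (nrow(expression) < 2L) stop("need >= 2 genes for percentile ranks")
  means <- rowMeans(expression, na.rm = TRUE)
  bad <- !is.finite(means)
  if (any(bad)) {
    warning("excluding ", sum(bad), " gene(s) with all-missing expression")
    means <- means[!bad]
  }
  rank(means, ties.method = "average") / length(means) * 100
}

#' Centered Pearson co-expression for gene pairs
#'
#' Correlation of two genes' mean-centered expression profiles across their
#' shared non-missing conditions (pairwise deletion).  Pairs with fewer than
#' `min_conditions` shared conditions, or with a gene missing from the
#' matrix, get `NA`.
#'
#' @param expression gene x condition matrix
#' @param pairs two-column matrix or data.frame of gene-id pairs
#' @param min_conditions minimum shared non-missing conditions (default 3)
#' @return numeric vector of correlations, one per pair row
#' @export
pair_coexpression <- function(expression, pairs, min_conditions = 3L) {
  pairs <- as.matrix(pairs)
  vapply(seq_len(nrow(pairs)), function(i) {
    g1 <- pairs[i, 1]; g2 <- pairs[i, 2]
    if (!g1 %in% rownames(expression) || !g2 %in% rownames(expression))
      return(NA_real_)
    x <- expression[g1, ]; y <- expression[g2, ]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < min_conditions) return(NA_real_)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])
  }, 0)
}

#' Compare co-expression of interacting vs non-interacting pairs
#'
#' Computes per-pair centered Pearson co-expression for the two pair sets,
#' their means and standard deviations, a Welch two-sample t-test (unequal
#' variances, two-tailed) on the difference, and a frequency-polygon table
#' (per-set fractions over bins spanning \[-1, 1\]).
#'
#' @param interacting_pairs,noninteracting_pairs two-column matrices of gene
#'   id pairs
#' @param expression gene x condition matrix
#' @param n_bins number of frequency-polygon bins over \[-1, 1\] (default 20)
#' @return list of class `coexpression_report`: per-set correlation vectors,
#'   `mean_interacting`, `sd_interacting`, `mean_noninteracting`,
#'   `sd_noninteracting`, `t_statistic`, `df`, `p_value`, and `polygon`
#'   (data.frame of bin centers and per-set fractions)
#' @export
compare_sets <- function(interacting_pairs, noninteracting_pairs,
                         expression, n_bins = 20L) {
  r_int <- pair_coexpression(expression, interacting_pairs)
  r_non <- pair_coexpression(expression, noninteracting_pairs)
  r_int <- r_int[is.finite(r_int)]
  r_non <- r_non[is.finite(r_non)]
  if (length(r_int) < 2L || length(r_non) < 2L)
    stop("each pair set needs >= 2 usable co-expression values")
  tt <- stats::t.test(r_int, r_non, var.equal = FALSE,
                      alternative = "two.sided")
  breaks <- seq(-1, 1, length.out = n_bins + 1L)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  frac <- function(v) {
    h <- graphics::hist(pmin(pmax(v, -1), 1), breaks = breaks,
                        plot = FALSE)
    h$counts / length(v)
  }
  structure(list(
    r_interacting = r_int,
    r_noninteracting = r_non,
    mean_interacting = mean(r_int), sd_interacting = stats::sd(r_int),
    mean_noninteracting = mean(r_non), sd_noninteracting = stats::sd(r_non),
    t_statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    polygon = data.frame(bin_center = centers,
                         frac_interacting = frac(r_int),
                         frac_noninteracting = frac(r_non))),
    class = "coexpression_report")
}

#' @export
print.coexpression_report <- function(x, ...) {
  cat(sprintf("co-expression: interacting %.2f+/-%.2f (n=%d) vs non-interacting %.2f+/-%.2f (n=%d)\n",
              x$mean_interacting, x$sd_interacting, length(x$r_interacting),
              x$mean_noninteracting, x$sd_noninteracting,
              length(x$r_noninteracting)))
  cat(sprintf("Welch two-tailed t-test: t = %.3f, df = %.1f, p = %.4g\n",
              x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Plot a co-expression report as a frequency polygon
#' @param x a `coexpression_report`
#' @param ... passed to [graphics::matplot()]
#' @export
plot.coexpression_report <- function(x, ...) {
  graphics::matplot(x$polygon$bin_center,
                    cbind(x$polygon$frac_interacting,
                          x$polygon$frac_noninteracting),
                    type = "b", pch = c(16, 1), lty = 1,
                    col = c("black", "red"),
                    xlab = "centered Pearson co-expression",
                    ylab = "fraction of pairs", ...)
  graphics::legend("topleft", pch = c(16, 1), col = c("black", "red"),
                   legend = c("interacting", "non-interacting"), bty = "n")
  invisible(x)
}

#' Interacting and non-interacting gene pairs of a network
#'
#' The interacting set is the network's high-confidence bait-prey edges; the
#' non-interacting set is, by default, every bait x observed-protein pair
#' not in the interacting set (self-pairs excluded); `universe = "all"`
#' takes all unordered pairs of observed proteins instead.
#'
#' @param network an `interaction_network`
#' @param observed_proteins proteins observed anywhere in the pull-down data
#' @param universe `"bait_observed"` (default) or `"all"`
#' @return list with two-column matrices `interacting` and `noninteracting`
#' @export
interaction_pair_sets <- function(network, observed_proteins,
                                  universe = c("bait_observed", "all")) {
  universe <- match.arg(universe)
  e <- network$edges
  interacting <- cbind(e$bait, e$prey)
  ikey <- c(paste(e$bait, e$prey, sep = "\r"),
            paste(e$prey, e$bait, sep = "\r"))
  if (universe == "bait_observed") {
    baits <- network$nodes$protein[network$nodes$is_bait]
    all_pairs <- expand.grid(bait = baits, prey = observed_proteins,
                             stringsAsFactors = FALSE)
    all_pairs <- all_pairs[all_pairs$bait != all_pairs$prey, , drop = FALSE]
  } else {
    idx <- utils::combn(observed_proteins, 2L)
    all_pairs <- data.frame(bait = idx[1, ], prey = idx[2, ],
                            stringsAsFactors = FALSE)
  }
  key <- paste(all_pairs$bait, all_pairs$prey, sep = "\r")
  non <- all_pairs[!key %in% ikey, , drop = FALSE]
  list(interacting = interacting,
       noninteracting = as.matrix(non))
}
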