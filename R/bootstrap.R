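#' Bootstrap test configuration
#'
#' Defaults are the study conditions the test was designed for: 10,000
#' resamples, pool screening at Pearson R < 0.3, and triples drawn with
#' replacement from each side (three biological replicates per pull-down).
#'
#' @param n_boot number of bootstrap resamples (>= 1)
#' @param r_threshold pool admission threshold on the Pearson correlation
#'   between a candidate replicate profile and every focal-bait replicate
#'   profile (candidate enters the null pool only if all correlations are
#'   below this)
#' @param sample_size values drawn with replacement from each side per
#'   resample
#' @param seed integer seed; each (bait, prey) pair gets its own stream
#'   derived from (seed, bait, prey), so row order never changes results
#' @return list of class `bootstrap_config`
#' @export
bootstrap_config <- function(n_boot = 10000L, r_threshold = 0.3,
                             sample_size = 3L, seed = 1L) {
  stopifnot(n_boot >= 1L, r_threshold >= 0, r_threshold <= 1,
            sample_size >= 1L)
  structure(list(n_boot = as.integer(n_boot), r_threshold = r_threshold,
                 sample_size = as.integer(sample_size),
                 seed = as.integer(seed)),
            class = "bootstrap_config")
}

# deterministic 31-bit stream seed from (seed, bait, prey)
derive_seed <- function(seed, bait, prey) {
  codes <- utf8ToInt(paste(bait, prey, sep = "\r"))
  h <- as.double(seed %% 2147483647L)
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Dense replicate profile
#'
#' One bait pull-down biological replicate as a vector over a fixed protein
#' index: the per-protein maximum emPAI over elution fractions, 0 where the
#' protein was not observed.  This is the unit object of the pool-screening
#' correlations and of the bootstrap resampling.
#'
#' @param x a [pulldown_matrix]
#' @param bait_id,replicate_id run to densify
#' @param proteins protein index to align to (default: all proteins in `x`)
#' @return named numeric vector over `proteins`
#' @export
replicate_profile <- function(x, bait_id, replicate_id,
                              proteins = pd_proteins(x)) {
  v <- max_over_fractions(x, bait_id, replicate_id)
  out <- stats::setNames(rep(0, length(proteins)), proteins)
  hit <- intersect(names(v), proteins)
  out[hit] <- v[hit]
  out
}

#' Null pool of dissimilar replicates for one bait
#'
#' Candidate replicates are every replicate of every other bait plus all
#' no-bait control replicates.  A candidate enters the pool iff its Pearson
#' correlation with every replicate profile of the focal bait is below
#' `config$r_threshold`; the bait's own replicates are always excluded.  A
#' correlation undefined because one profile is constant is treated as 0
#' (maximally uninformative, hence admissible).
#'
#' @param x a [pulldown_matrix]
#' @param bait_id focal bait
#' @param config a [bootstrap_config]
#' @return list with `profiles` (proteins x pool-members matrix) and
#'   `members` (data.frame of `source_bait`, `replicate`)
#' @export
build_null_pool <- function(x, bait_id, config = bootstrap_config()) {
  proteins <- pd_proteins(x)
  own <- lapply(pd_replicates(x, bait_id), function(r)
    replicate_profile(x, bait_id, r, proteins))
  others <- c(setdiff(pd_baits(x), bait_id),
              if (pd_has_control(x)) pd_control_id(x))
  members <- list()
  profiles <- list()
  for (b in others) {
    for (r in pd_replicates(x, b)) {
      cand <- replicate_profile(x, b, r, proteins)
      cors <- vapply(own, function(p) {
        if (stats::sd(cand) == 0 || stats::sd(p) == 0) return(0)
        stats::cor(cand, p)
      }, 0)
      if (all(cors < config$r_threshold)) {
        members[[length(members) + 1L]] <-
          data.frame(source_bait = b, replicate = r)
        profiles[[length(profiles) + 1L]] <- cand
      }
    }
  }
  if (!length(members))
    stop("empty null pool for bait '", bait_id,
         "': every candidate replicate correlates >= ", config$r_threshold,
         " with a focal replicate; consider raising r_threshold")
  list(profiles = do.call(cbind, profiles),
       members = do.call(rbind, members))
}

row_medians <- function(m) {
  if (ncol(m) == 3L) {
    m[, 1] + m[, 2] + m[, 3] - pmax(m[, 1], m[, 2], m[, 3]) -
      pmin(m[, 1], m[, 2], m[, 3])
  } else {
    apply(m, 1L, stats::median)
  }
}

#' Bootstrap p-value for one (bait, prey) pair
#'
#' Repeats `n_boot` times: draw `sample_size` values with replacement from
#' the bait's replicate maxima for the prey and the same number from the
#' prey's values across the null-pool replicates, and count the resamples
#' `n` in which the bait median strictly exceeds the pool median.  The
#' p-value is `1 - n / n_boot`; ties favor the null, which makes the test
#' conservative.
#'
#' @param bait_values numeric vector of length `config$sample_size`
#'   (per-replicate maxima, 0 for replicates without the prey)
#' @param pool_values prey values across the pool replicates (0 where the
#'   prey was absent from a pool replicate)
#' @param config a [bootstrap_config]
#' @param stream_seed integer seed for this pair's stream (defaults to
#'   `config$seed`)
#' @return one-row data.frame with `n_exceed`, `p_value`, `pool_size`
#' @export
bootstrap_pvalue <- function(bait_values, pool_values,
                             config = bootstrap_config(),
                             stream_seed = config$seed) {
  if (length(bait_values) != config$sample_size)
    stop("need exactly sample_size bait values")
  if (!length(pool_values)) stop("empty pool values")
  set.seed(stream_seed)
  s <- config$sample_size
  B <- config$n_boot
  bm <- matrix(sample(bait_values, B * s, replace = TRUE), B, s)
  pm <- matrix(sample(pool_values, B * s, replace = TRUE), B, s)
  n_exceed <- sum(row_medians(bm) > row_medians(pm))
  data.frame(n_exceed = n_exceed, p_value = 1 - n_exceed / B,
             pool_size = length(pool_values))
}

#' Bootstrap significance for every observed (bait, prey) pair
#'
#' Runs [bootstrap_pvalue()] for each protein observed in each bait's
#' pull-downs, including the bait protein itself (significant baits are an
#' internal positive control: the bait should be the most abundant protein
#' in its own purification).  The null pool is built once per bait; a bait
#' whose pool is empty (every candidate replicate correlates at or above
#' `r_threshold` with a focal replicate) gets `NA` p-values with a warning
#' -- the test is undefined for it rather than the whole table failing.
#'
#' @param x a [pulldown_matrix]
#' @param config a [bootstrap_config]
#' @return data.frame of class `bootstrap_result` with one row per (bait,
#'   protein observed for that bait): `bait`, `protein`, `n_exceed`,
#'   `p_value`, `pool_size`
#' @export
significance_table <- function(x, config = bootstrap_config()) {
  proteins <- pd_proteins(x)
  rows <- list()
  for (b in pd_baits(x)) {
    pool <- tryCatch(build_null_pool(x, b, config), error = function(e) {
      warning("bait '", b, "': ", conditionMessage(e),
              "; reporting NA p-values", call. = FALSE)
      NULL
    })
    reps <- pd_replicates(x, b)
    own <- vapply(reps, function(r) replicate_profile(x, b, r, proteins),
                  numeric(length(proteins)))
    own <- matrix(own, nrow = length(proteins),
                  dimnames = list(proteins, NULL))
    observed <- proteins[rowSums(own) > 0]
    for (p in observed) {
      res <- if (is.null(pool)) {
        data.frame(n_exceed = NA_integer_, p_value = NA_real_,
                   pool_size = 0L)
      } else {
        bootstrap_pvalue(own[match(p, proteins), ],
                         pool$profiles[p, ],
                         config,
                         stream_seed = derive_seed(config$seed, b, p))
      }
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(bait = b, protein = p), res)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("bootstrap_result", "data.frame")
  out
}
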