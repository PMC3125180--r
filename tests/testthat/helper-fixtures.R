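# fixture builders shared across test files

# long-format entry rows from a compact spec: list(protein, bait, rep, frac, value)
pm_entries <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(protein = r[[1]], bait = r[[2]], replicate = as.integer(r[[3]]),
               fraction = as.integer(r[[4]]), empai = as.numeric(r[[5]]),
               stringsAsFactors = FALSE)))
}

# a bait pull-down in which `values` is a named list protein -> per-replicate
# maxima (length k); each value is planted in fraction 1 of its replicate,
# NA meaning "absent from that replicate"
bait_block <- function(bait, values, k = 3L) {
  rows <- list()
  for (p in names(values)) {
    v <- values[[p]]
    for (r in seq_len(k)) {
      if (!is.na(v[r]))
        rows[[length(rows) + 1L]] <- list(p, bait, r, 1L, v[r])
    }
  }
  do.call(pm_entries, rows)
}

# small randomized pulldown matrix for property tests
random_pulldown <- function(seed, n_baits = 3L, n_proteins = 12L,
                            n_reps = 3L, n_fracs = 4L, density = 0.4,
                            with_control = TRUE) {
  set.seed(seed)
  proteins <- sprintf("P%02d", seq_len(n_proteins))
  baits <- sprintf("B%d", seq_len(n_baits))
  ids <- c(baits, if (with_control) apmsnet::CONTROL_ID)
  rows <- expand.grid(protein = proteins, bait = ids,
                      replicate = seq_len(n_reps),
                      fraction = seq_len(n_fracs),
                      stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(rows)) < density
  rows <- rows[keep, , drop = FALSE]
  rows$empai <- round(stats::rexp(nrow(rows), rate = 1), 4)
  # guarantee every bait keeps replicate 1 so replicate ids stay contiguous
  anchor <- expand.grid(protein = proteins[1], bait = ids,
                        replicate = seq_len(n_reps), fraction = 1L,
                        stringsAsFactors = FALSE)
  anchor$empai <- 0.5
  rows <- rbind(rows, anchor)
  rows <- rows[!duplicated(rows[c("protein", "bait", "replicate", "fraction")]), ]
  pulldown_matrix(rows, baits = baits)
}
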