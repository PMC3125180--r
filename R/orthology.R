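#' Reciprocal best hits between two proteomes
#'
#' Operational ortholog assignment: protein a (species A) and b (species B)
#' are orthologs iff b is a's best hit in the A-vs-B table, a is b's best
#' hit in the B-vs-A table, and both e-values pass the cutoff.  Best hits
#' are chosen by minimum e-value, ties broken by higher bitscore, then
#' lexicographically smaller subject id.
#'
#' @param hits_ab,hits_ba similarity hit tables as from [read_hits()]
#'   (columns `query`, `subject`, `evalue`, optional `bitscore`)
#' @param evalue_cutoff maximum e-value in both directions (default 1e-4)
#' @return data.frame of class `ortholog_map` with columns `a`, `b`,
#'   `evalue_ab`, `evalue_ba`; the mapping is one-to-one
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, evalue_cutoff = 1e-4) {
  best <- function(h) {
    if (!"bitscore" %in% names(h)) h$bitscore <- NA_real_
    o <- order(h$query, h$evalue,
               -ifelse(is.na(h$bitscore), -Inf, h$bitscore), h$subject)
    h <- h[o, , drop = FALSE]
    h[!duplicated(h$query), , drop = FALSE]
  }
  ab <- best(hits_ab)
  ba <- best(hits_ba)
  ab <- ab[ab$evalue <= evalue_cutoff, , drop = FALSE]
  ba <- ba[ba$evalue <= evalue_cutoff, , drop = FALSE]
  back <- stats::setNames(ba$subject, ba$query)
  keep <- !is.na(back[ab$subject]) & back[ab$subject] == ab$query
  keep[is.na(keep)] <- FALSE
  out <- data.frame(a = ab$query[keep], b = ab$subject[keep],
                    evalue_ab = ab$evalue[keep],
                    evalue_ba = ba$evalue[match(ab$subject[keep], ba$query)],
                    stringsAsFactors = FALSE)
  o <- order(out$a)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ortholog_map", "data.frame")
  out
}

#' Orthologous-interaction coverage
#'
#' Given a species-A interaction network, a reference set of interacting
#' protein pairs in species B, and an A<->B ortholog map: the *expected*
#' interactions are the reference pairs whose two members both map to
#' species-A proteins appearing as bait or prey in the network and whose
#' mapped bait-side ortholog is one of the study's baits; the *shared*
#' interactions are those also present in the network in either direction.
#' Self-self pairs are excluded on both sides.
#'
#' @param network_a an `interaction_network` in species A
#' @param reference_edges_b two-column matrix/data.frame of unordered
#'   species-B interacting pairs
#' @param ortholog_map an `ortholog_map` with species A in column `a`
#' @param bait_set_a bait proteins of the species-A study (default: the
#'   network's bait nodes)
#' @return list `(shared, expected, fraction)`; `fraction` is `NA` when
#'   nothing is expected
#' @export
interaction_coverage <- function(network_a, reference_edges_b, ortholog_map,
                                 bait_set_a = network_a$nodes$protein[network_a$nodes$is_bait]) {
  ref <- as.matrix(reference_edges_b)
  if (nrow(ref) == 0L || nrow(ortholog_map) == 0L)
    return(list(shared = 0L, expected = 0L, fraction = NA_real_))
  b2a <- stats::setNames(ortholog_map$a, ortholog_map$b)
  a1 <- b2a[ref[, 1]]
  a2 <- b2a[ref[, 2]]
  e <- network_a$edges
  in_study <- unique(c(e$bait, e$prey, bait_set_a))
  ok <- !is.na(a1) & !is.na(a2) & a1 != a2 &
    a1 %in% in_study & a2 %in% in_study &
    (a1 %in% bait_set_a | a2 %in% bait_set_a)
  a1 <- a1[ok]; a2 <- a2[ok]
  ukey <- ifelse(a1 < a2, paste(a1, a2, sep = "\r"),
                 paste(a2, a1, sep = "\r"))
  dup <- duplicated(ukey)
  a1 <- a1[!dup]; a2 <- a2[!dup]; ukey <- ukey[!dup]
  expected <- length(ukey)
  if (expected == 0L)
    return(list(shared = 0L, expected = 0L, fraction = NA_real_))
  obs_ukey <- ifelse(e$bait < e$prey, paste(e$bait, e$prey, sep = "\r"),
                     paste(e$prey, e$bait, sep = "\r"))
  shared <- sum(ukey %in% obs_ukey)
  list(shared = shared, expected = expected,
       fraction = shared / expected)
}
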