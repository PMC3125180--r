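#' Parameters for in-silico digestion and observable-peptide counting
#'
#' Defaults match the study design the package emulates: fully tryptic
#' peptides with up to one missed cleavage; "observable" peptides are those
#' of 6-30 residues with no mass filter (the observable criterion of the
#' original search engine is not recoverable, so it is configuration, not
#' fact, and is recorded in output metadata).
#'
#' @param missed_cleavages maximum number of missed cleavage sites (>= 0).
#' @param min_len,max_len peptide length bounds in residues.
#' @param min_mass,max_mass monoisotopic mass bounds in Da.
#' @return list of class `empai_params`
#' @export
empai_params <- function(missed_cleavages = 1L, min_len = 6L, max_len = 30L,
                         min_mass = 0, max_mass = Inf) {
  stopifnot(missed_cleavages >= 0, min_len <= max_len, min_mass <= max_mass)
  structure(list(missed_cleavages = as.integer(missed_cleavages),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 min_mass = min_mass, max_mass = max_mass),
            class = "empai_params")
}

# monoisotopic residue masses (Da); X is unknown and disqualifies mass filters
MONO_MASS <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
               V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
               I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
               K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
               F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
WATER_MONO <- 18.010565

peptide_mass <- function(pep) {
  aa <- strsplit(pep, "", fixed = TRUE)[[1]]
  if (any(aa == "X")) return(NA_real_)
  m <- MONO_MASS[aa]
  if (anyNA(m)) return(NA_real_)
  sum(m) + WATER_MONO
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine (K) or arginine (R) except when the next
#' residue is proline (P), and returns all fully tryptic products with up to
#' `params$missed_cleavages` internal missed sites, terminal peptides
#' included.  The KP suppression matters in practice: a short protein whose
#' only internal K is followed by P (the rubredoxin case) yields a single
#' tryptic peptide and hence a minimal observable count.
#'
#' @param sequence protein sequence (uppercase amino acids; X tolerated).
#' @param params an [empai_params]
#' @return character vector of distinct peptide sequences
#' @export
digest <- function(sequence, params = empai_params()) {
  sequence <- toupper(as.character(sequence))
  if (is.na(sequence) || nchar(sequence) == 0L)
    stop("empty protein sequence")
  if (grepl("[^A-Z]", sequence))
    stop("protein sequence contains non-letter characters")
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  # cut after position i if aa[i] in {K, R} and aa[i+1] != P
  cuts <- which(aa %in% c("K", "R"))
  cuts <- cuts[cuts < n & aa[pmin(cuts + 1L, n)] != "P" | cuts == n]
  cuts <- cuts[cuts < n]                     # terminal cut is implicit
  bounds <- c(0L, cuts, n)                   # fragment i spans bounds[i]+1..bounds[i+1]
  nfrag <- length(bounds) - 1L
  peps <- character(0)
  for (i in seq_len(nfrag)) {
    for (m in 0:params$missed_cleavages) {
      j <- i + m
      if (j > nfrag) break
      peps <- c(peps, substr(sequence, bounds[i] + 1L, bounds[j + 1L]))
    }
  }
  unique(peps)
}

#' Count observable peptides of a protein
#'
#' Number of distinct in-silico digestion products passing the length and
#' mass filters in `params`.  Peptides containing "X" have undefined mass and
#' fail any finite mass filter.
#'
#' @inheritParams digest
#' @return integer count
#' @export
count_observable <- function(sequence, params = empai_params()) {
  peps <- digest(sequence, params)
  len_ok <- nchar(peps) >= params$min_len & nchar(peps) <= params$max_len
  if (params$min_mass > 0 || is.finite(params$max_mass)) {
    mass <- vapply(peps, peptide_mass, 0)
    mass_ok <- !is.na(mass) & mass >= params$min_mass & mass <= params$max_mass
  } else {
    mass_ok <- TRUE
  }
  sum(len_ok & mass_ok)
}

#' Exponentially modified protein abundance index
#'
#' `emPAI = 10^(n_observed / n_observable) - 1`, the label-free relative
#' abundance proxy used throughout the pipeline.  `n_observed` is capped at
#' `n_observable` before forming the ratio (modified or missed-cleavage
#' variants can push the raw observed count above the nominal observable
#' count), so emPAI is bounded by 9.
#'
#' @param n_observed distinct observed peptides (>= 0)
#' @param n_observable distinct observable peptides (>= 1)
#' @return non-negative emPAI value
#' @export
compute_empai <- function(n_observed, n_observable) {
  if (any(n_observable < 1L))
    stop("n_observable must be >= 1: emPAI undefined for proteins with no observable peptides")
  if (any(n_observed < 0)) stop("n_observed must be >= 0")
  ratio <- pmin(n_observed, n_observable) / n_observable
  10^ratio - 1
}

#' Compute a pull-down matrix from peptide identifications
#'
#' Aggregates peptide observations per (protein, bait, replicate, fraction)
#' cell, counting distinct peptide sequences (charge states and modified
#' forms collapse), and converts each count to an emPAI value against the
#' protein's observable-peptide count from in-silico digestion of the
#' supplied proteome.
#'
#' @param observations data.frame with columns `protein`, `peptide`, `bait`,
#'   `replicate`, `fraction`.
#' @param proteome named character vector of protein sequences, or a FASTA
#'   file path (read with Biostrings).
#' @param params an [empai_params]
#' @param control_id reserved control bait id
#' @return a [pulldown_matrix]; observed peptides that are not products of
#'   their protein's digest are reported with a warning (and still counted).
#' @export
quantify <- function(observations, proteome, params = empai_params(),
                     control_id = CONTROL_ID) {
  need <- c("protein", "peptide", "bait", "replicate", "fraction")
  if (!all(need %in% names(observations)))
    stop("observations need columns ", paste(need, collapse = ", "))
  if (is.character(proteome) && length(proteome) == 1L &&
      file.exists(proteome))
    proteome <- read_proteome(proteome)
  absent <- setdiff(unique(observations$protein), names(proteome))
  if (length(absent))
    stop("protein id(s) absent from proteome: ",
         paste(absent, collapse = ", "))
  digests <- lapply(proteome[unique(observations$protein)], digest,
                    params = params)
  stray <- mapply(function(p, pep) !pep %in% digests[[p]],
                  observations$protein, observations$peptide)
  if (any(stray))
    warning(sum(stray), " observed peptide(s) are not products of their ",
            "protein's in-silico digest")
  key <- interaction(observations$protein, observations$bait,
                     observations$replicate, observations$fraction,
                     drop = TRUE, sep = "\r")
  n_observed <- tapply(observations$peptide, key,
                       function(s) length(unique(s)))
  parts <- strsplit(names(n_observed), "\r", fixed = TRUE)
  prot <- vapply(parts, `[[`, "", 1L)
  n_observable <- vapply(unique(observations$protein),
                         function(p) count_observable(proteome[[p]], params),
                         0L)
  if (any(n_observable[prot] < 1L))
    stop("protein(s) with zero observable peptides: ",
         paste(unique(prot[n_observable[prot] < 1L]), collapse = ", "))
  entries <- data.frame(
    protein = prot,
    bait = vapply(parts, `[[`, "", 2L),
    replicate = as.integer(vapply(parts, `[[`, "", 3L)),
    fraction = as.integer(vapply(parts, `[[`, "", 4L)),
    empai = compute_empai(as.integer(n_observed), n_observable[prot]),
    stringsAsFactors = FALSE)
  pm <- pulldown_matrix(entries, control_id = control_id)
  attr(pm, "empai_params") <- params
  pm
}

#' Read a protein FASTA as a named character vector
#' @param path FASTA file path
#' @export
read_proteome <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  # FASTA descriptions: keep the id token only
  names(out) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1L)
  out
}
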