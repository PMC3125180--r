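#' Reserved bait identifier for the no-bait control
#'
#' Control purifications (untagged strain over the same affinity column) are
#' stored in the same [pulldown_matrix] as the bait pull-downs, under this
#' reserved bait id, so that every downstream operation sees one data model.
#' @export
CONTROL_ID <- "__CONTROL__"

#' Sparse emPAI pull-down matrix
#'
#' The raw experimental observable of an AP-MS study: a sparse map from
#' (protein, bait, biological replicate, elution fraction) to an emPAI
#' abundance value.  Absence of a key means "not observed in that run", which
#' is distinct from an explicit zero; no reader or writer in this package ever
#' converts missingness to 0 silently.
#'
#' @param entries data.frame with columns `protein`, `bait`, `replicate`,
#'   `fraction`, `empai`.  `replicate` and `fraction` are coerced to integer,
#'   `empai` must be finite and non-negative.
#' @param baits optional character vector fixing the bait order; defaults to
#'   the order of first appearance, control last.
#' @param control_id reserved bait id holding the no-bait control runs.
#' @return An object of class `pulldown_matrix`: the long-format entry table
#'   with attributes `baits` (ordered, control excluded) and `control_id`.
#' @examples
#' pm <- pulldown_matrix(data.frame(
#'   protein = "DVU0001", bait = "ApsA", replicate = 1L,
#'   fraction = 1L, empai = 0.5))
#' @export
pulldown_matrix <- function(entries, baits = NULL, control_id = CONTROL_ID) {
  required <- c("protein", "bait", "replicate", "fraction", "empai")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols))
    stop("pulldown entries lack column(s): ", paste(missing_cols, collapse = ", "))
  entries <- as.data.frame(entries)[required]
  entries$protein <- as.character(entries$protein)
  entries$bait <- as.character(entries$bait)
  entries$replicate <- as.integer(entries$replicate)
  entries$fraction <- as.integer(entries$fraction)
  entries$empai <- as.numeric(entries$empai)
  if (anyNA(entries))
    stop("pulldown entries contain NA values")
  if (any(entries$empai < 0))
    stop("negative emPAI values are not allowed")
  key <- paste(entries$protein, entries$bait, entries$replicate,
               entries$fraction, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (protein, bait, replicate, fraction) entries")
  seen <- unique(entries$bait)
  seen <- c(setdiff(seen, control_id),
            intersect(control_id, seen))
  if (is.null(baits)) {
    baits <- setdiff(seen, control_id)
  } else {
    baits <- setdiff(as.character(baits), control_id)
    extra <- setdiff(setdiff(seen, control_id), baits)
    if (length(extra))
      stop("entries contain baits not in 'baits': ", paste(extra, collapse = ", "))
  }
  for (b in unique(entries$bait)) {
    reps <- sort(unique(entries$replicate[entries$bait == b]))
    if (!identical(reps, seq_len(max(reps))))
      stop("replicate ids for bait '", b,
           "' are not contiguous starting at 1")
  }
  # canonical row order keeps all writers deterministic
  o <- order(entries$bait, entries$replicate, entries$fraction, entries$protein)
  entries <- entries[o, , drop = FALSE]
  rownames(entries) <- NULL
  structure(entries, baits = baits, control_id = control_id,
            class = c("pulldown_matrix", "data.frame"))
}

#' @export
print.pulldown_matrix <- function(x, ...) {
  cat("pulldown_matrix: ", nrow(x), " emPAI entries, ",
      length(pd_baits(x)), " baits, ",
      length(unique(x$protein)), " proteins",
      if (pd_has_control(x)) ", control present" else ", no control",
      "\n", sep = "")
  invisible(x)
}

#' Baits of a pull-down matrix (control excluded)
#' @param x a [pulldown_matrix]
#' @return character vector of bait ids in their stored order.
#' @export
pd_baits <- function(x) attr(x, "baits")

#' Control id of a pull-down matrix
#' @param x a [pulldown_matrix]
#' @export
pd_control_id <- function(x) attr(x, "control_id")

#' Does the matrix contain no-bait control runs?
#' @param x a [pulldown_matrix]
#' @export
pd_has_control <- function(x) any(x$bait == pd_control_id(x))

#' Replicate ids observed for one bait
#' @param x a [pulldown_matrix]
#' @param bait_id bait (or control) id
#' @export
pd_replicates <- function(x, bait_id) {
  sort(unique(x$replicate[x$bait == bait_id]))
}

#' All proteins observed anywhere in the matrix
#' @param x a [pulldown_matrix]
#' @return sorted character vector
#' @export
pd_proteins <- function(x) sort(unique(x$protein))

#' Look up one emPAI value
#'
#' @param x a [pulldown_matrix]
#' @param protein,bait,replicate,fraction key of the entry
#' @return the emPAI value, or `NA` if the key was not observed (never 0).
#' @export
pd_value <- function(x, protein, bait, replicate, fraction) {
  hit <- x$protein == protein & x$bait == bait &
    x$replicate == replicate & x$fraction == fraction
  if (!any(hit)) return(NA_real_)
  x$empai[hit][1L]
}
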