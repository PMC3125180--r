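#' Dialect configuration for pull-down tables
#'
#' Pull-down tables are wide: one protein-id column plus one abundance column
#' per (bait, replicate, fraction) run.  The canonical header grammar is
#' `<bait>|r<rep>|f<frac>` (e.g. `ApsA|r2|f5`).  Tables that store
#' pre-maximized values (one column per bait replicate, the maximum over
#' elution fractions already taken) are read with `premaximized = TRUE`, in
#' which case headers are `<bait>|r<rep>` and every value lands in fraction 1.
#'
#' @param sep field separator, `"\t"` or `","`.
#' @param id_column name of the protein-id column (default: first column).
#' @param premaximized logical; see above.
#' @return a list of class `pulldown_dialect`.
#' @export
pulldown_dialect <- function(sep = "\t", id_column = NULL,
                             premaximized = FALSE) {
  stopifnot(sep %in% c("\t", ","))
  structure(list(sep = sep, id_column = id_column,
                 premaximized = isTRUE(premaximized)),
            class = "pulldown_dialect")
}

parse_run_header <- function(h, premaximized) {
  parts <- strsplit(h, "|", fixed = TRUE)[[1]]
  n_expect <- if (premaximized) 2L else 3L
  bad <- function() stop("unparsable pull-down column header: '", h, "'",
                         call. = FALSE)
  if (length(parts) != n_expect) bad()
  rep_part <- parts[2]
  if (!grepl("^r[0-9]+$", rep_part)) bad()
  replicate <- as.integer(sub("^r", "", rep_part))
  if (premaximized) {
    fraction <- 1L
  } else {
    if (!grepl("^f[0-9]+$", parts[3])) bad()
    fraction <- as.integer(sub("^f", "", parts[3]))
  }
  list(bait = parts[1], replicate = replicate, fraction = fraction)
}

#' Read a wide emPAI pull-down table
#'
#' Every non-empty numeric cell becomes one entry of the resulting
#' [pulldown_matrix]; empty cells stay absent ("not observed").  Malformed
#' numeric cells are reported with row and column coordinates.
#'
#' @param path file path (TSV or CSV per the dialect).
#' @param dialect a [pulldown_dialect].
#' @param control_id reserved bait id for no-bait control columns.
#' @return a [pulldown_matrix]
#' @export
read_pulldown_table <- function(path, dialect = pulldown_dialect(),
                                control_id = CONTROL_ID) {
  tab <- utils::read.delim(path, sep = dialect$sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 1L) stop("pull-down table has no columns")
  id_col <- dialect$id_column
  if (is.null(id_col)) id_col <- names(tab)[1]
  if (!id_col %in% names(tab))
    stop("protein-id column '", id_col, "' not found")
  proteins <- tab[[id_col]]
  if (anyDuplicated(proteins))
    stop("duplicate protein rows: ",
         paste(unique(proteins[duplicated(proteins)]), collapse = ", "))
  run_cols <- setdiff(names(tab), id_col)
  headers <- lapply(run_cols, parse_run_header,
                    premaximized = dialect$premaximized)
  out <- vector("list", length(run_cols))
  for (j in seq_along(run_cols)) {
    raw <- tab[[run_cols[j]]]
    present <- !is.na(raw) & trimws(raw) != ""
    vals <- suppressWarnings(as.numeric(raw[present]))
    if (anyNA(vals)) {
      bad_rows <- which(present)[is.na(vals)]
      stop("malformed numeric cell(s) in column '", run_cols[j],
           "', data row(s) ", paste(bad_rows, collapse = ", "))
    }
    if (any(vals < 0))
      stop("negative emPAI value in column '", run_cols[j], "'")
    h <- headers[[j]]
    out[[j]] <- data.frame(protein = proteins[present], bait = h$bait,
                           replicate = h$replicate, fraction = h$fraction,
                           empai = vals, stringsAsFactors = FALSE)
  }
  entries <- do.call(rbind, out)
  if (is.null(entries) || nrow(entries) == 0L)
    entries <- data.frame(protein = character(), bait = character(),
                          replicate = integer(), fraction = integer(),
                          empai = numeric())
  bait_order <- unique(vapply(headers, `[[`, "", "bait"))
  pulldown_matrix(entries, baits = setdiff(bait_order, control_id),
                  control_id = control_id)
}

#' Write a pull-down matrix as a wide table
#'
#' Column order is deterministic: baits in their stored order (control last),
#' replicates and fractions ascending.  Unobserved cells are written empty so
#' a re-read reproduces the matrix exactly.
#'
#' @param x a [pulldown_matrix]
#' @param path output file path
#' @param dialect a [pulldown_dialect]
#' @export
write_pulldown_table <- function(x, path, dialect = pulldown_dialect()) {
  bait_order <- c(pd_baits(x),
                  if (pd_has_control(x)) pd_control_id(x))
  proteins <- pd_proteins(x)
  cols <- list()
  headers <- character()
  for (b in bait_order) {
    sub_b <- x[x$bait == b, , drop = FALSE]
    for (r in sort(unique(sub_b$replicate))) {
      sub_r <- sub_b[sub_b$replicate == r, , drop = FALSE]
      fracs <- if (dialect$premaximized) 1L else sort(unique(sub_r$fraction))
      for (f in fracs) {
        sub_f <- sub_r[sub_r$fraction == f, , drop = FALSE]
        v <- rep("", length(proteins))
        idx <- match(sub_f$protein, proteins)
        v[idx] <- sprintf("%.17g", sub_f$empai)
        # trim float noise where the short form parses back identically
        short <- sprintf("%.15g", sub_f$empai)
        ok <- as.numeric(short) == sub_f$empai
        v[idx[ok]] <- short[ok]
        h <- if (dialect$premaximized) sprintf("%s|r%d", b, r)
             else sprintf("%s|r%d|f%d", b, r, f)
        headers <- c(headers, h)
        cols[[h]] <- v
      }
    }
  }
  lines <- paste(c("protein", headers), collapse = dialect$sep)
  if (length(proteins)) {
    body <- do.call(cbind, c(list(proteins), cols))
    lines <- c(lines, apply(body, 1L, paste, collapse = dialect$sep))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(NULL)
}

#' Read a protein-to-functional-role annotation table
#'
#' Two-column TSV with header `protein<TAB>role` (e.g. TIGR functional
#' roles).  Extra columns are ignored with a warning.  Proteins without an
#' annotation are simply absent from the map.
#'
#' @param path file path
#' @return named character vector mapping protein id to role label
#' @export
read_roles <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("role table needs at least 2 columns")
  if (ncol(tab) > 2L)
    warning("role table: ignoring extra column(s) ",
            paste(names(tab)[-(1:2)], collapse = ", "))
  if (anyDuplicated(tab[[1]]))
    stop("duplicate protein rows in role table")
  stats::setNames(tab[[2]], tab[[1]])
}

#' Read a gene-by-condition expression matrix
#'
#' TSV with gene ids in the first column and one column per condition;
#' values are normalized log2 ratios, empty cells are missing.
#'
#' @param path file path
#' @return numeric matrix, genes in rows, conditions in columns
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(tab[[1]]))
    stop("duplicate gene rows in expression matrix")
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  if (anyDuplicated(colnames(m)))
    stop("duplicate condition columns in expression matrix")
  m
}

#' Read an all-vs-all similarity hit table
#'
#' Accepts either a headered TSV with columns `query`, `subject`, `evalue`
#' (optionally `bitscore`), or headerless BLAST tabular output (outfmt 6,
#' 12 columns).  Only the best row per (query, subject) pair is retained
#' (minimum e-value, ties broken by higher bitscore).
#'
#' @param path file path
#' @return data.frame with columns `query`, `subject`, `evalue`, `bitscore`
#' @export
read_hits <- function(path) {
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  headered <- any(c("query", "evalue") %in% fields)
  if (headered) {
    tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
    needed <- c("query", "subject", "evalue")
    if (!all(needed %in% names(tab)))
      stop("hit table must have columns query, subject, evalue")
    extra <- setdiff(names(tab), c(needed, "bitscore"))
    if (length(extra))
      warning("hit table: ignoring extra column(s) ",
              paste(extra, collapse = ", "))
    if (!"bitscore" %in% names(tab)) tab$bitscore <- NA_real_
  } else {
    tab <- utils::read.delim(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 12L)
      stop("headerless hit table must be 12-column BLAST outfmt 6")
    tab <- data.frame(query = as.character(tab[[1]]),
                      subject = as.character(tab[[2]]),
                      evalue = tab[[11]], bitscore = tab[[12]],
                      stringsAsFactors = FALSE)
  }
  tab$evalue <- suppressWarnings(as.numeric(tab$evalue))
  tab$bitscore <- suppressWarnings(as.numeric(tab$bitscore))
  if (anyNA(tab$evalue)) stop("non-numeric e-values in hit table")
  if (any(tab$evalue < 0)) stop("negative e-values in hit table")
  tab <- tab[, c("query", "subject", "evalue", "bitscore")]
  # keep the single best row per (query, subject)
  o <- order(tab$query, tab$subject, tab$evalue,
             -ifelse(is.na(tab$bitscore), -Inf, tab$bitscore))
  tab <- tab[o, , drop = FALSE]
  key <- paste(tab$query, tab$subject, sep = "\r")
  tab <- tab[!duplicated(key), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
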