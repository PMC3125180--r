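#' Convert an interaction network to an igraph graph
#'
#' Directed graph with vertex attributes `role`, `is_bait`,
#' `bait_prominence` and edge attributes `weight` (pseudo-confidence score;
#' dashed edges carry the conventional sentinel width 0.001), `score`,
#' `dashed`, `reciprocal`, `p_value`.
#'
#' @param network an `interaction_network`
#' @export
as_igraph <- function(network) {
  nodes <- network$nodes
  e <- network$edges
  vert <- data.frame(name = nodes$protein,
                     role = ifelse(is.na(nodes$role), "", nodes$role),
                     is_bait = as.integer(nodes$is_bait),
                     bait_prominence = nodes$bait_prominence,
                     stringsAsFactors = FALSE)
  edf <- data.frame(from = e$bait, to = e$prey,
                    weight = ifelse(e$dashed, 0.001, e$score),
                    score = e$score,
                    dashed = as.integer(e$dashed),
                    reciprocal = as.integer(e$reciprocal),
                    p_value = e$p_value,
                    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vert)
}

#' Write an interaction network to file
#'
#' Supported formats:
#' \describe{
#'   \item{`pajek_net`}{Pajek `.net`; arc weight is the pseudo-confidence
#'     score, dashed (equal-to-control) edges get the arbitrary sentinel
#'     width 0.001.}
#'   \item{`sif`}{Cytoscape SIF with relation `pulls_down`.}
#'   \item{`graphml`}{GraphML via igraph, carrying role, bait-flag, score,
#'     dashed and reciprocal attributes.}
#'   \item{`edge_tsv`}{plain TSV edge list with all edge columns.}
#' }
#' All writers are deterministic: vertices and edges are emitted in sorted
#' order.
#'
#' @param network an `interaction_network`
#' @param path output file
#' @param format one of `"pajek_net"`, `"sif"`, `"graphml"`, `"edge_tsv"`
#' @export
write_network <- function(network, path,
                          format = c("pajek_net", "sif", "graphml",
                                     "edge_tsv")) {
  format <- match.arg(format)
  nodes <- network$nodes
  e <- network$edges
  switch(format,
    pajek_net = {
      idx <- stats::setNames(seq_len(nrow(nodes)), nodes$protein)
      w <- ifelse(e$dashed, 0.001, e$score)
      lines <- c(sprintf("*Vertices %d", nrow(nodes)),
                 sprintf('%d "%s"', seq_len(nrow(nodes)), nodes$protein),
                 "*Arcs",
                 sprintf("%d %d %.6g", idx[e$bait], idx[e$prey], w))
      writeLines(lines, path, useBytes = TRUE)
    },
    sif = {
      writeLines(sprintf("%s\tpulls_down\t%s", e$bait, e$prey), path,
                 useBytes = TRUE)
    },
    graphml = {
      igraph::write_graph(as_igraph(network), path, format = "graphml")
    },
    edge_tsv = {
      utils::write.table(e, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  invisible(NULL)
}
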