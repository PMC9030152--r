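# Protein-protein interaction handling: confidence/channel edge filtering
# and extraction of the RBP x breast-cancer bipartite network with hub
# statistics.

PPI_CHANNELS <- c("experimental", "database", "textmining", "coexpression", "other")

validate_edges <- function(edges) {
  need <- c("gene_a", "gene_b", "channel", "score")
  if (!all(need %in% names(edges)))
    stop("edge table must have columns gene_a, gene_b, channel, score")
  if (nrow(edges) && any(edges$score < 0 | edges$score > 1))
    stop("interaction scores must lie in [0, 1]")
  edges
}

#' Filter scored edges by evidence channel and confidence
#'
#' Keeps an edge row iff its channel is allowed and its score reaches the
#' threshold (inclusive). The default reproduces the highest-confidence
#' STRING-style selection: experimental and database evidence at score
#' >= 0.9.
#'
#' @param edges Data frame gene_a/gene_b/channel/score.
#' @param allowed_channels Channels to keep.
#' @param min_score Inclusive confidence threshold.
#' @return The filtered edge data frame.
#' @export
filter_edges <- function(edges,
                         allowed_channels = c("experimental", "database"),
                         min_score = 0.9) {
  edges <- validate_edges(edges)
  keep <- edges$channel %in% allowed_channels & edges$score >= min_score
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the bipartite network between two gene sets
#'
#' Retains only edges joining a breast-cancer-set gene to an RBP-set gene.
#' Genes belonging to both sets are reported in the `dual` element and may
#' appear on both sides.
#'
#' @param edges Edge data frame (typically already [filter_edges()]-ed).
#' @param bc_set,rbp_set Character vectors (or `$genes` lists).
#' @return Object of class `bipartite_net`: list with `edges`, `left_degree`
#'   (BC side), `right_degree` (RBP side), `dual` (genes in both sets that
#'   appear in the network).
#' @export
extract_bipartite <- function(edges, bc_set, rbp_set) {
  edges <- validate_edges(edges)
  bc <- as_gene_vector(bc_set)
  rbp <- as_gene_vector(rbp_set)
  a_bc <- edges$gene_a %in% bc
  b_bc <- edges$gene_b %in% bc
  a_rbp <- edges$gene_a %in% rbp
  b_rbp <- edges$gene_b %in% rbp
  cross <- (a_bc & b_rbp) | (a_rbp & b_bc)
  kept <- edges[cross, , drop = FALSE]
  rownames(kept) <- NULL

  deg <- function(side_set) {
    nodes <- c(kept$gene_a[kept$gene_a %in% side_set],
               kept$gene_b[kept$gene_b %in% side_set])
    tab <- table(nodes)
    stats::setNames(as.integer(tab), names(tab))
  }
  left_degree <- deg(bc)
  right_degree <- deg(rbp)
  dual <- intersect(intersect(bc, rbp),
                    unique(c(kept$gene_a, kept$gene_b)))
  structure(list(edges = kept, left_degree = left_degree,
                 right_degree = right_degree, dual = sort(dual)),
            class = "bipartite_net")
}

#' @export
print.bipartite_net <- function(x, ...) {
  cat(sprintf("Bipartite PPI network: %d edges, %d BC proteins x %d RBPs\n",
              nrow(x$edges), length(x$left_degree), length(x$right_degree)))
  if (length(x$dual))
    cat("  genes in both sets:", paste(x$dual, collapse = ", "), "\n")
  invisible(x)
}

#' Interactor counts and hub ranking
#'
#' @param net A [extract_bipartite()] result.
#' @return List with `n_left` and `n_right` (connected genes per side) and
#'   `hubs` (data frame gene/degree, BC-side genes in descending degree,
#'   ties broken lexicographically).
#' @export
interactor_counts <- function(net) {
  stopifnot(inherits(net, "bipartite_net"))
  ld <- net$left_degree
  if (is.null(names(ld))) names(ld) <- character(0)
  ord <- order(-ld, names(ld))
  list(n_left = sum(ld >= 1L),
       n_right = sum(net$right_degree >= 1L),
       hubs = data.frame(gene = names(ld)[ord],
                         degree = as.integer(ld[ord]),
                         stringsAsFactors = FALSE, row.names = NULL))
}
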