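# Disease-gene network construction around prioritized seeds and a
# from-scratch MCODE implementation: k-core-based vertex weighting,
# seed-and-expand complex detection (vertex weight percentage cutoff,
# optional haircut and fluff), and complex-catalog annotation.

#' Build the filtered disease gene network around seed genes
#'
#' Takes the one-hop neighborhood of the seed genes in a weighted
#' functional network and keeps only nodes that are RBPs, cancer driver
#' genes, or seeds. Seeds absent from the network are reported (attribute
#' `missing_seeds`) and retained as isolated vertices. Node class labels
#' (`seed`, `both`, `rbp`, `cdg`) are attached as a vertex attribute.
#'
#' @param funcnet Data frame gene_a/gene_b (+ optional weight column).
#' @param seeds Character vector of seed genes.
#' @param rbp_set,cdg_set Character vectors (or `$genes` lists) used to
#'   filter the neighborhood.
#' @return An undirected simple `igraph` graph with vertex attribute
#'   `class`; empty (with a warning) when nothing survives the filter.
#' @export
build_disease_network <- function(funcnet, seeds, rbp_set, cdg_set) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(funcnet)))
  seeds <- unique(as.character(seeds))
  rbp <- as_gene_vector(rbp_set)
  cdg <- as_gene_vector(cdg_set)
  g <- igraph::graph_from_data_frame(funcnet, directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "max", "ignore"))
  nodes <- igraph::V(g)$name
  present <- intersect(seeds, nodes)
  missing <- setdiff(seeds, nodes)
  if (length(missing))
    warning("seed(s) absent from the functional network: ",
            paste(missing, collapse = ", "))
  nbrs <- if (length(present)) {
    unique(nodes[unlist(igraph::adjacent_vertices(g, present))])
  } else character(0)
  keep <- intersect(union(present, nbrs), union(union(rbp, cdg), seeds))
  sub <- igraph::induced_subgraph(g, keep)
  add <- setdiff(seeds, igraph::V(sub)$name)
  if (length(add)) sub <- igraph::add_vertices(sub, length(add), name = add)
  if (igraph::vcount(sub) == 0L) warning("empty disease network")
  nm <- igraph::V(sub)$name
  cls <- ifelse(nm %in% seeds, "seed",
         ifelse(nm %in% rbp & nm %in% cdg, "both",
         ifelse(nm %in% rbp, "rbp", "cdg")))
  igraph::V(sub)$class <- cls
  attr(sub, "missing_seeds") <- missing
  sub
}

#' MCODE vertex weight
#'
#' The weight of a vertex is k x density of the highest k-core of its
#' closed neighborhood, where density = 2|E| / (|V|(|V|-1)). Isolated
#' vertices weigh 0. Edge weights are ignored: the algorithm is
#' topological.
#'
#' @param graph An undirected `igraph` graph.
#' @param v A vertex name or index.
#' @return The vertex weight (non-negative real).
#' @export
mcode_vertex_weight <- function(graph, v) {
  vi <- if (is.character(v)) match(v, igraph::V(graph)$name) else as.integer(v)
  if (is.na(vi) || vi < 1L || vi > igraph::vcount(graph))
    stop("no such vertex: ", v)
  nb <- as.integer(igraph::neighbors(graph, vi))
  vs <- unique(c(vi, nb))
  sub <- igraph::induced_subgraph(graph, vs)
  if (igraph::ecount(sub) == 0L) return(0)
  core <- igraph::coreness(sub)
  k <- max(core)
  ksub <- igraph::induced_subgraph(sub, which(core == k))
  nv <- igraph::vcount(ksub)
  density <- 2 * igraph::ecount(ksub) / (nv * (nv - 1))
  k * density
}

#' MCODE weights for every vertex
#'
#' @param graph An undirected `igraph` graph.
#' @return Named numeric vector of [mcode_vertex_weight()] values.
#' @export
mcode_weights <- function(graph) {
  n <- igraph::vcount(graph)
  w <- vapply(seq_len(n), function(i) mcode_vertex_weight(graph, i), numeric(1))
  stats::setNames(w, igraph::V(graph)$name)
}

#' Find dense complexes by seeded expansion (MCODE)
#'
#' Vertices are weighted by [mcode_vertex_weight()] and visited as seeds in
#' descending weight order (ties broken lexicographically). From each
#' unvisited seed, breadth-first expansion adds unvisited neighbors whose
#' weight is at least `seed_weight * (1 - node_score_cutoff)`. Every vertex
#' joins at most one complex. With `haircut`, degree-1 members of a complex
#' are removed; with `fluff > 0`, unvisited neighbors whose closed
#' neighborhood density exceeds the fluff threshold are added. Complexes of
#' fewer than two members are discarded.
#'
#' @param graph An undirected `igraph` graph.
#' @param node_score_cutoff Vertex weight percentage in \[0, 1).
#' @param fluff Fluff density threshold (0 disables fluff).
#' @param haircut Remove degree-1 complex members?
#' @return List of complexes in descending score order; each is a list with
#'   `members` (sorted), `seed`, `score` (density x size), `n_edges`.
#' @export
mcode_find_complexes <- function(graph, node_score_cutoff = 0.1, fluff = 0,
                                 haircut = FALSE) {
  if (node_score_cutoff < 0 || node_score_cutoff >= 1)
    stop("node_score_cutoff must lie in [0, 1)")
  if (fluff < 0 || fluff > 1) stop("fluff must lie in [0, 1]")
  n <- igraph::vcount(graph)
  if (n == 0L) return(list())
  nm <- igraph::V(graph)$name
  w <- mcode_weights(graph)
  adj <- igraph::as_adj_list(graph)
  adj <- lapply(adj, function(v) unique(as.integer(v)))
  visited <- rep(FALSE, n)
  complexes <- list()

  for (s in order(-w, nm)) {
    if (visited[s]) next
    thr <- w[s] * (1 - node_score_cutoff)
    visited[s] <- TRUE
    members <- s
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      for (u in adj[[v]]) {
        if (!visited[u] && w[u] >= thr) {
          visited[u] <- TRUE
          members <- c(members, u)
          queue <- c(queue, u)
        }
      }
    }
    if (haircut && length(members) > 1L) {
      sub <- igraph::induced_subgraph(graph, members)
      members <- members[igraph::degree(sub) >= 2L]
    }
    if (fluff > 0 && length(members)) {
      fringe <- setdiff(unique(unlist(adj[members])), members)
      fringe <- fringe[!visited[fringe]]
      for (u in fringe) {
        nbu <- unique(c(u, adj[[u]]))
        subu <- igraph::induced_subgraph(graph, nbu)
        nvu <- igraph::vcount(subu)
        dens <- if (nvu < 2L) 0 else 2 * igraph::ecount(subu) / (nvu * (nvu - 1))
        if (dens > fluff) {
          visited[u] <- TRUE
          members <- c(members, u)
        }
      }
    }
    if (length(members) >= 2L) {
      sub <- igraph::induced_subgraph(graph, members)
      nv <- igraph::vcount(sub)
      dens <- 2 * igraph::ecount(sub) / (nv * (nv - 1))
      complexes[[length(complexes) + 1L]] <-
        list(members = sort(nm[members]), seed = nm[s],
             score = dens * nv, n_edges = igraph::ecount(sub))
    }
  }
  ord <- order(-vapply(complexes, `[[`, numeric(1), "score"),
               vapply(complexes, `[[`, character(1), "seed"))
  complexes[ord]
}

#' Annotate a complex against a catalog of known complexes
#'
#' Finds the catalog entry sharing the most members with a predicted
#' complex; ties are broken by higher coverage, then lexicographic name.
#'
#' @param members Character vector: members of the predicted complex (or a
#'   complex list from [mcode_find_complexes()]).
#' @param catalog Named list of gene vectors (e.g. from [read_gmt()]).
#' @return List with `catalog_name`, `n_matched`, `coverage`
#'   (n_matched / complex size); `NULL` with a warning when the catalog is
#'   empty.
#' @export
annotate_complex <- function(members, catalog) {
  if (is.list(members) && !is.null(members$members)) members <- members$members
  members <- unique(as.character(members))
  if (!length(catalog)) {
    warning("empty complex catalog; no annotation")
    return(NULL)
  }
  n_matched <- vapply(catalog, function(set) length(intersect(members, set)),
                      integer(1))
  coverage <- n_matched / length(members)
  ord <- order(-n_matched, -coverage, names(catalog))
  best <- ord[1L]
  list(catalog_name = names(catalog)[best],
       n_matched = unname(n_matched[best]),
       coverage = unname(coverage[best]))
}
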