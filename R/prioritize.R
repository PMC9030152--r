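# Four-criteria evidence intersection: per-gene evidence vectors over (1)
# first-quartile alteration burden, (2) filtered PPI with a breast-cancer
# protein, (3) IHC shift toward over-(or under-)expression, (4) essentiality
# in either loss-of-function screen; then the intersection producing the
# prioritized and near-miss sets with a full Venn breakdown.

#' Build per-gene evidence vectors
#'
#' Assembles, for every gene of the universe, the four boolean criteria
#' from the upstream module outputs. In the suppression direction criterion
#' 1 should be computed from the suppression alteration profile, and
#' criterion 3 means a shift of at least one level toward
#' underexpression — pass the matching gene sets.
#'
#' @param universe Character vector: the genes being prioritized (the RBP
#'   set).
#' @param quartile_genes Genes in the first quartile of profile alteration
#'   counts (criterion 1).
#' @param ppi_genes Genes with at least one filtered interaction with a
#'   breast-cancer protein (criterion 2).
#' @param ihc_genes Genes whose IHC shift points in the analyzed direction
#'   (criterion 3: delta >= +1 for progression, <= -1 for suppression).
#' @param essential_genes Union essential set over both screens
#'   (criterion 4).
#' @param direction `"progression"` or `"suppression"`, recorded on the
#'   result.
#' @return Data frame gene/c1_quartile/c2_ppi/c3_ihc/c4_essential/direction.
#' @export
build_evidence <- function(universe, quartile_genes, ppi_genes, ihc_genes,
                           essential_genes,
                           direction = c("progression", "suppression")) {
  direction <- match.arg(direction)
  universe <- as_gene_vector(universe)
  crit <- list(quartile = as_gene_vector(quartile_genes),
               ppi = as_gene_vector(ppi_genes),
               ihc = as_gene_vector(ihc_genes),
               essential = as_gene_vector(essential_genes))
  stray <- sort(unique(unlist(lapply(crit, setdiff, y = universe))))
  if (length(stray))
    stop("criterion genes outside the gene universe: ",
         paste(utils::head(stray, 10L), collapse = ", "),
         if (length(stray) > 10L) ", ...")
  data.frame(gene = universe,
             c1_quartile = universe %in% crit$quartile,
             c2_ppi = universe %in% crit$ppi,
             c3_ihc = universe %in% crit$ihc,
             c4_essential = universe %in% crit$essential,
             direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Intersect the four evidence criteria
#'
#' @param evidence An evidence data frame from [build_evidence()].
#' @return Object of class `prioritization`: list with `prioritized` (all
#'   four criteria), `near_miss` (criteria 1-3 but not essential),
#'   `venn_counts` (named counts over all 15 non-empty criterion
#'   combinations; they sum to the number of genes meeting at least one
#'   criterion), and `direction`.
#' @export
prioritize_intersect <- function(evidence) {
  need <- c("gene", "c1_quartile", "c2_ppi", "c3_ihc", "c4_essential")
  stopifnot(all(need %in% names(evidence)))
  m <- as.matrix(evidence[, c("c1_quartile", "c2_ppi", "c3_ihc", "c4_essential")])
  crit_names <- c("c1", "c2", "c3", "c4")
  combos <- character(0)
  counts <- integer(0)
  for (mask in 1:15) {
    on <- as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L)))
    in_combo <- apply(m, 1L, function(r) all(r == on))
    combos <- c(combos, paste(crit_names[on], collapse = "&"))
    counts <- c(counts, sum(in_combo))
  }
  prioritized <- sort(evidence$gene[rowSums(m) == 4L])
  near_miss <- sort(evidence$gene[m[, 1L] & m[, 2L] & m[, 3L] & !m[, 4L]])
  structure(list(prioritized = prioritized,
                 near_miss = near_miss,
                 venn_counts = stats::setNames(counts, combos),
                 direction = evidence$direction[1L] %||% NA_character_),
            class = "prioritization")
}

#' @export
print.prioritization <- function(x, ...) {
  cat(sprintf("Prioritization (%s direction)\n", x$direction))
  cat(sprintf("  %d genes meet all four criteria: %s\n",
              length(x$prioritized), paste(x$prioritized, collapse = ", ")))
  cat(sprintf("  %d near-miss genes (criteria 1-3, not essential)\n",
              length(x$near_miss)))
  invisible(x)
}
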