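# Essentiality calling from loss-of-function dependency screens: gene-level
# mean scores, the depleting-direction threshold, screen union/intersection
# accounting, and per-subtype essential and subtype-exclusive sets.

#' Call essential genes from a dependency-score matrix
#'
#' A gene is called essential when its mean dependency score across the
#' considered cell lines is at or below `-threshold` — i.e. the depletion
#' effect exceeds the threshold magnitude (a CERES/DEMETER2-style sign
#' convention, where strongly negative means the line depends on the gene).
#' Genes with no non-missing score in the subset are excluded and reported.
#'
#' @param mat Numeric cell line x gene matrix (row names = cell lines,
#'   column names = genes; NA allowed).
#' @param lines Optional subset of cell-line names to use.
#' @param threshold Positive threshold magnitude (default 0.5, inclusive).
#' @param screen Optional screen label echoed into the result.
#' @return Data frame gene/mean_score/essential/n_lines (+ `screen` when
#'   given), with attribute `excluded` (all-missing genes).
#' @export
call_essential <- function(mat, lines = NULL, threshold = 0.5, screen = NULL) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (threshold <= 0) stop("threshold must be > 0")
  if (!is.null(lines)) {
    missing <- setdiff(lines, rownames(mat))
    if (length(missing))
      stop("unknown cell line(s): ", paste(missing, collapse = ", "))
    if (!length(lines)) stop("empty cell-line subset")
    mat <- mat[lines, , drop = FALSE]
  }
  n_lines <- colSums(!is.na(mat))
  excluded <- colnames(mat)[n_lines == 0L]
  keep <- n_lines > 0L
  mean_score <- colMeans(mat[, keep, drop = FALSE], na.rm = TRUE)
  out <- data.frame(gene = colnames(mat)[keep],
                    mean_score = unname(mean_score),
                    essential = unname(mean_score <= -threshold),
                    n_lines = unname(n_lines[keep]),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(screen)) out$screen <- screen
  attr(out, "excluded") <- excluded
  out
}

essential_set <- function(x) {
  if (is.data.frame(x)) sort(x$gene[x$essential]) else sort(unique(as.character(x)))
}

#' Combine essentiality calls from two screens
#'
#' @param calls_rnai,calls_crispr [call_essential()] data frames, or plain
#'   character vectors of essential genes.
#' @return List with `union`, `intersection`, `rnai`, `crispr` gene sets;
#'   sizes satisfy inclusion-exclusion exactly.
#' @export
combine_screens <- function(calls_rnai, calls_crispr) {
  a <- essential_set(calls_rnai)
  b <- essential_set(calls_crispr)
  list(union = sort(union(a, b)),
       intersection = sort(intersect(a, b)),
       rnai = a,
       crispr = b)
}

#' Essential genes per molecular subtype, with subtype-exclusive sets
#'
#' Runs [call_essential()] on each subtype's cell lines. A gene is
#' exclusive to a subtype when it is essential there and in no other
#' subtype; exclusive sets are therefore pairwise disjoint. Subtypes with
#' no annotated lines in the matrix are skipped and reported.
#'
#' @param mat Cell line x gene dependency matrix.
#' @param annotations Data frame with columns cell_line, subtype.
#' @param threshold Threshold magnitude passed to [call_essential()].
#' @return List with `essential` (named list of gene sets per subtype),
#'   `exclusive` (named list), and `skipped` (subtypes without lines).
#' @export
essential_by_subtype <- function(mat, annotations, threshold = 0.5) {
  stopifnot(all(c("cell_line", "subtype") %in% names(annotations)))
  ann <- annotations[annotations$cell_line %in% rownames(mat), , drop = FALSE]
  subtypes <- sort(unique(annotations$subtype))
  skipped <- setdiff(subtypes, unique(ann$subtype))
  used <- setdiff(subtypes, skipped)
  essential <- lapply(used, function(s) {
    essential_set(call_essential(mat, lines = ann$cell_line[ann$subtype == s],
                                 threshold = threshold))
  })
  names(essential) <- used
  exclusive <- lapply(used, function(s) {
    others <- unlist(essential[setdiff(used, s)], use.names = FALSE)
    setdiff(essential[[s]], others)
  })
  names(exclusive) <- used
  list(essential = essential, exclusive = exclusive, skipped = skipped)
}
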