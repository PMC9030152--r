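# Ordinal immunohistochemistry: the 4-level scale, modal consensus calling
# over tumor samples, and shift classification between normal and tumor
# tissue.

IHC_LEVEL_LABELS <- c("not_detected", "low", "medium", "high")

#' The ordinal IHC scale
#'
#' @return Named integer vector mapping level labels to 0..3.
#' @export
ihc_levels <- function() {
  stats::setNames(0:3, IHC_LEVEL_LABELS)
}

#' Coerce IHC levels to the 0..3 integer scale
#'
#' @param x Character labels (`not_detected`, `low`, `medium`, `high`) or
#'   integers already on 0..3.
#' @return Integer vector on 0..3.
#' @export
as_ihc_level <- function(x) {
  if (is.character(x) || is.factor(x)) {
    v <- match(as.character(x), IHC_LEVEL_LABELS) - 1L
    if (anyNA(v)) stop("unknown IHC level label: ",
                       paste(unique(x[is.na(v)]), collapse = ", "))
    return(v)
  }
  v <- as.integer(x)
  if (anyNA(v) || any(v < 0L | v > 3L))
    stop("IHC levels must lie on the 0..3 ordinal scale")
  v
}

ihc_level_label <- function(v) IHC_LEVEL_LABELS[as.integer(v) + 1L]

#' Consensus IHC level over tumor samples
#'
#' The modal level of the sample multiset; among tied modes the higher
#' ordinal level is returned (a deterministic rule, applied symmetrically,
#' standing in for the manual frequency-based consensus used on real
#' pathology data). Permutation-invariant, and invariant under duplicating
#' every sample k times.
#'
#' @param tumor_levels Non-empty vector of levels (labels or 0..3).
#' @return The consensus level label.
#' @export
consensus_level <- function(tumor_levels) {
  if (!length(tumor_levels)) stop("empty tumor level multiset")
  v <- as_ihc_level(tumor_levels)
  freq <- tabulate(v + 1L, nbins = 4L)
  best <- which(freq == max(freq))  # ties resolved toward the higher level
  ihc_level_label(max(best) - 1L)
}

#' Classify the normal-to-tumor expression shift
#'
#' delta = tumor - normal on the ordinal scale; |delta| >= 2 is a strong
#' shift (upregulated / downregulated), |delta| = 1 a moderate one.
#'
#' @param normal_level,tumor_consensus Levels (labels or 0..3).
#' @return List with `delta` (integer) and `label` (one of `upregulated`,
#'   `moderate_up`, `unchanged`, `moderate_down`, `downregulated`).
#' @export
classify_shift <- function(normal_level, tumor_consensus) {
  d <- as_ihc_level(tumor_consensus) - as_ihc_level(normal_level)
  label <- ifelse(d >= 2, "upregulated",
           ifelse(d == 1, "moderate_up",
           ifelse(d == 0, "unchanged",
           ifelse(d == -1, "moderate_down", "downregulated"))))
  list(delta = as.integer(d), label = label)
}

#' Flag at least one variation level toward overexpression
#'
#' @param delta Integer level shift(s) (tumor - normal).
#' @return Logical: `delta >= 1`.
#' @export
overexpression_flag <- function(delta) {
  as.integer(delta) >= 1L
}

#' Per-gene IHC shift table
#'
#' Computes, for every gene with both a normal measurement and at least one
#' tumor sample, the normal level, tumor consensus, shift delta and shift
#' class. Genes lacking either tissue are excluded and reported in the
#' `excluded` attribute.
#'
#' @param ihc Data frame with columns gene, tissue (`normal`/`tumor`),
#'   sample_id, level.
#' @return Data frame gene/normal/tumor_consensus/delta/class, with
#'   attribute `excluded` (character vector of dropped genes).
#' @export
ihc_shift_table <- function(ihc) {
  need <- c("gene", "tissue", "level")
  if (!all(need %in% names(ihc)))
    stop("IHC table must have columns gene, tissue, level")
  if (!all(ihc$tissue %in% c("normal", "tumor")))
    stop("tissue must be 'normal' or 'tumor'")
  genes <- sort(unique(ihc$gene))
  has_normal <- genes %in% ihc$gene[ihc$tissue == "normal"]
  has_tumor <- genes %in% ihc$gene[ihc$tissue == "tumor"]
  keep <- genes[has_normal & has_tumor]
  excluded <- setdiff(genes, keep)

  normal_by <- split(ihc$level[ihc$tissue == "normal"],
                     ihc$gene[ihc$tissue == "normal"])
  tumor_by <- split(ihc$level[ihc$tissue == "tumor"],
                    ihc$gene[ihc$tissue == "tumor"])
  normal <- vapply(keep, function(g) consensus_level(normal_by[[g]]), character(1))
  tumor <- vapply(keep, function(g) consensus_level(tumor_by[[g]]), character(1))
  shift <- classify_shift(normal, tumor)
  out <- data.frame(gene = keep, normal = normal, tumor_consensus = tumor,
                    delta = shift$delta, class = shift$label,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- excluded
  out
}

#' Cross-tabulate normal against tumor consensus levels
#'
#' The 4 x 4 gene-count matrix behind the normal-versus-tumor correlation
#' plot: entries sum to the number of classified genes and the diagonal
#' holds the unchanged genes.
#'
#' @param shifts A shift table from [ihc_shift_table()] (or any data frame
#'   with `normal` and `tumor_consensus` level columns).
#' @return 4 x 4 integer matrix, rows = normal level, columns = tumor
#'   consensus level.
#' @export
crosstab_levels <- function(shifts) {
  stopifnot(all(c("normal", "tumor_consensus") %in% names(shifts)))
  tab <- table(factor(shifts$normal, levels = IHC_LEVEL_LABELS),
               factor(shifts$tumor_consensus, levels = IHC_LEVEL_LABELS))
  m <- matrix(as.integer(tab), 4L, 4L,
              dimnames = list(normal = IHC_LEVEL_LABELS,
                              tumor = IHC_LEVEL_LABELS))
  m
}
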