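# Alteration-burden profiling: per-gene event counts under the
# progression/suppression category profiles, normalized burden per patient
# and per clinical group, rank-based comparisons, and the first-quartile
# selection of most-altered genes.

#' The closed alteration-category vocabulary
#'
#' cBioPortal-style event classes for one (sample, gene) pair.
#' @export
ALTERATION_CATEGORIES <- c("amplification", "deep_deletion", "mrna_up",
                           "mrna_down", "mutation", "fusion")

#' Alteration-category profile
#'
#' The progression profile groups the categories associated with
#' tumor-promoting behavior (amplification, mRNA upregulation, fusion,
#' mutation); the suppression profile groups deep deletion, mRNA
#' downregulation, fusion and mutation. Fusions and mutations belong to
#' both profiles.
#'
#' @param name `"progression"` or `"suppression"`.
#' @return List with `name` and `categories`.
#' @export
profile_spec <- function(name = c("progression", "suppression")) {
  name <- match.arg(name)
  categories <- switch(name,
    progression = c("amplification", "mrna_up", "fusion", "mutation"),
    suppression = c("deep_deletion", "mrna_down", "fusion", "mutation"))
  list(name = name, categories = categories)
}

validate_calls <- function(calls) {
  need <- c("sample_id", "gene", "category")
  if (!all(need %in% names(calls)))
    stop("alteration calls must have columns sample_id, gene, category")
  bad <- which(!calls$category %in% ALTERATION_CATEGORIES)
  if (length(bad))
    stop(sprintf("unknown alteration category '%s' in row %d",
                 calls$category[bad[1L]], bad[1L]))
  calls
}

#' Count alteration events per gene under a profile
#'
#' Events are counted, not altered patients: a gene-sample pair with two
#' profile categories contributes two.
#'
#' @param calls Data frame of alteration calls (sample_id, gene, category).
#' @param profile A [profile_spec()] or its name.
#' @param universe Optional gene vector; genes without events are reported
#'   with count 0.
#' @return Named integer vector of event counts.
#' @export
count_per_gene <- function(calls, profile = "progression", universe = NULL) {
  calls <- validate_calls(calls)
  if (is.character(profile)) profile <- profile_spec(profile)
  hits <- calls[calls$category %in% profile$categories, , drop = FALSE]
  counts <- table(factor(hits$gene,
                         levels = if (is.null(universe)) sort(unique(hits$gene))
                                  else as_gene_vector(universe)))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Per-patient alteration burden normalized by gene-set size
#'
#' For each patient, the number of alteration rows involving a gene of the
#' set divided by the set size, so sets of different sizes are comparable.
#'
#' @param calls Alteration calls.
#' @param geneset Character vector (or `$genes` list) of set members.
#' @param samples Optional sample annotation data frame; when given,
#'   patients without events appear with burden 0.
#' @return Named numeric vector of burdens (events / |geneset|).
#' @export
burden_per_patient <- function(calls, geneset, samples = NULL) {
  calls <- validate_calls(calls)
  genes <- as_gene_vector(geneset)
  if (!length(genes)) stop("empty geneset")
  ids <- sort(unique(c(calls$sample_id,
                       if (!is.null(samples)) samples$sample_id)))
  hits <- calls[calls$gene %in% genes, , drop = FALSE]
  counts <- table(factor(hits$sample_id, levels = ids))
  out <- as.numeric(counts) / length(genes)
  names(out) <- ids
  out
}

#' Alteration burden per clinical group
#'
#' Total events of samples in each subtype or stage, divided by the number
#' of patients annotated to the group. Groups without patients are absent.
#'
#' @param calls Alteration calls.
#' @param samples Sample annotations (sample_id, subtype, stage).
#' @param group `"subtype"` or `"stage"`.
#' @param geneset Optional restriction of events to a gene set.
#' @return Named numeric vector of burdens (events / patients in group).
#' @export
burden_by_group <- function(calls, samples, group = c("subtype", "stage"),
                            geneset = NULL) {
  calls <- validate_calls(calls)
  group <- match.arg(group)
  if (!group %in% names(samples))
    stop("samples table lacks column: ", group)
  if (!is.null(geneset))
    calls <- calls[calls$gene %in% as_gene_vector(geneset), , drop = FALSE]
  labels <- samples[[group]][match(calls$sample_id, samples$sample_id)]
  if (anyNA(labels))
    stop("alteration calls reference samples missing from the annotation table")
  present <- sort(unique(samples[[group]]))
  events <- table(factor(labels, levels = present))
  n_patients <- table(factor(samples[[group]], levels = present))
  out <- as.numeric(events) / as.numeric(n_patients)
  names(out) <- present
  out
}

#' Mann-Whitney U rank comparison
#'
#' The U statistic counts pairs (x_i, y_j) with x_i > y_j, ties counted a
#' half. For small tie-free samples (both sizes <= 8) the two-sided p-value
#' is exact, from the enumeration distribution of U over all labelings;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Numeric samples, both non-empty.
#' @return Object of class `rank_test`: list with `u_statistic`, `p_value`,
#'   `method` (`"exact"` or `"normal_approx"`), `n1`, `n2`.
#' @export
mann_whitney <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("empty sample")
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L

  if (!ties && n1 <= 8L && n2 <= 8L) {
    p_low <- stats::pwilcox(u, n1, n2)
    p_high <- 1 - stats::pwilcox(u - 1, n1, n2)
    p <- min(1, 2 * min(p_low, p_high))
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(c(x, y))
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  structure(list(u_statistic = u, p_value = p, method = method,
                 n1 = n1, n2 = n2),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney rank test (%s): U = %g (n1 = %d, n2 = %d), p = %.4g\n",
              x$method, x$u_statistic, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' Genes in the first quartile of alteration counts
#'
#' Returns the genes whose count reaches the 75th percentile of the count
#' distribution (linear interpolation between order statistics, the default
#' quantile definition), boundary ties included. The selection always
#' contains at least a quarter of the genes.
#'
#' @param counts Named numeric vector of per-gene counts.
#' @return Character vector of selected genes, sorted.
#' @export
first_quartile_genes <- function(counts) {
  if (!length(counts)) stop("empty counts")
  thr <- unname(stats::quantile(counts, 0.75, type = 7))
  sort(names(counts)[counts >= thr])
}

#' Fraction of alteration events per category
#'
#' @param calls Alteration calls.
#' @param geneset Optional restriction to a gene set.
#' @return Named numeric vector over the full category vocabulary, summing
#'   to 1; empty (length 0) with a warning when no calls remain.
#' @export
category_breakdown <- function(calls, geneset = NULL) {
  calls <- validate_calls(calls)
  if (!is.null(geneset))
    calls <- calls[calls$gene %in% as_gene_vector(geneset), , drop = FALSE]
  if (!nrow(calls)) {
    warning("no alteration calls in the requested gene set; empty breakdown")
    return(stats::setNames(numeric(0), character(0)))
  }
  tab <- table(factor(calls$category, levels = ALTERATION_CATEGORIES))
  out <- as.numeric(tab) / nrow(calls)
  names(out) <- ALTERATION_CATEGORIES
  out
}
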