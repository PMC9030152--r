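# Gene-set and driver-catalog handling: GMT/TSV readers, duplicate
# collapsing, and the RBP x driver-role cross-tabulation.

#' Read a GMT file
#'
#' @param path Path to a GMT file (one set per line: name, description,
#'   then genes, tab-separated).
#' @return Named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty gene-set file: ", path)
  fgsea::gmtPathways(path)
}

#' Write a GMT file
#'
#' @param sets Named list of character gene vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a symbol/stable-id gene table
#'
#' Reads a one- or two-column TSV: gene symbol, optionally followed by a
#' stable identifier (e.g. an Ensembl gene id). Lines with more than two
#' fields are rejected with their line number.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `symbol`, `stable_id` (NA when absent).
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines_keep <- which(nzchar(trimws(lines)))
  if (!length(lines_keep)) stop("empty gene-set file: ", path)
  fields <- strsplit(lines[lines_keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) > 2L | lengths(fields) < 1L)
  if (length(bad))
    stop(sprintf("malformed gene-set line %d in %s: expected 1-2 tab-separated fields",
                 lines_keep[bad[1L]], path))
  data.frame(
    symbol = vapply(fields, `[`, character(1), 1L),
    stable_id = vapply(fields, function(f) if (length(f) >= 2L) f[2L] else NA_character_,
                       character(1)),
    stringsAsFactors = FALSE
  )
}

#' Collapse duplicate gene entries
#'
#' Two entries are duplicates when they share a stable identifier or a
#' case-normalized symbol (connected components of the shared-identifier
#' relation are merged). The first occurrence is kept; the report lists one
#' (kept, dropped) pair per collapsed entry. The operation is idempotent.
#'
#' @param genes Data frame with columns `symbol` and optionally `stable_id`
#'   (as from [read_gene_table()]), or a character vector of symbols.
#' @return List with `genes` (data frame of kept entries) and `report`
#'   (data frame kept/dropped symbols; zero rows when no duplicates).
#' @export
dedup_genes <- function(genes) {
  if (is.character(genes))
    genes <- data.frame(symbol = genes, stable_id = NA_character_,
                        stringsAsFactors = FALSE)
  stopifnot(is.data.frame(genes), "symbol" %in% names(genes))
  if (is.null(genes$stable_id)) genes$stable_id <- NA_character_
  n <- nrow(genes)
  if (n == 0L) stop("empty gene table")

  # union-find over entries linked by shared symbol or shared stable id
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  link_by <- function(key) {
    ok <- !is.na(key) & nzchar(key)
    for (grp in split(which(ok), key[ok])) {
      if (length(grp) > 1L) {
        r <- find(grp[1L])
        for (j in grp[-1L]) parent[find(j)] <<- r
      }
    }
  }
  link_by(toupper(trimws(genes$symbol)))
  link_by(genes$stable_id)

  root <- vapply(seq_len(n), find, integer(1))
  rep_idx <- tapply(seq_len(n), root, min)
  keeper <- as.integer(rep_idx[as.character(root)])
  dropped <- which(seq_len(n) != keeper)
  report <- data.frame(kept = genes$symbol[keeper[dropped]],
                       dropped = genes$symbol[dropped],
                       stringsAsFactors = FALSE)
  list(genes = genes[sort(unique(keeper)), , drop = FALSE], report = report)
}

#' Load and deduplicate a gene set
#'
#' Reads a gene set from GMT or TSV, collapses duplicate entries, and
#' returns the cleaned set together with the collapse report.
#'
#' @param path Path to a `.gmt` file (first set taken unless `set` names
#'   one) or a symbol/stable-id TSV.
#' @param name Name of the resulting set (defaults to the GMT set name or
#'   the file name).
#' @param set For GMT input, which set to load.
#' @return List with `name`, `genes` (character vector of kept symbols),
#'   `report` (data frame of collapsed duplicates).
#' @export
load_geneset <- function(path, name = NULL, set = NULL) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    sets <- read_gmt(path)
    if (is.null(set)) set <- names(sets)[1L]
    if (!set %in% names(sets)) stop("no such set in GMT: ", set)
    tab <- data.frame(symbol = sets[[set]], stable_id = NA_character_,
                      stringsAsFactors = FALSE)
    if (is.null(name)) name <- set
  } else {
    tab <- read_gene_table(path)
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  }
  dd <- dedup_genes(tab)
  list(name = name, genes = dd$genes$symbol, report = dd$report)
}

#' Read a cancer-driver catalog
#'
#' @param path TSV with columns gene, role (oncogene / tumor_suppressor /
#'   unknown), cancer_type.
#' @return Validated data frame.
#' @export
read_driver_catalog <- function(path) {
  cat <- read_tsv(path)
  validate_driver_catalog(cat)
}

validate_driver_catalog <- function(cat) {
  need <- c("gene", "role", "cancer_type")
  if (!all(need %in% names(cat)))
    stop("driver catalog must have columns gene, role, cancer_type")
  bad <- setdiff(unique(cat$role), c("oncogene", "tumor_suppressor", "unknown"))
  if (length(bad)) stop("unknown driver role(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(cat[c("gene", "cancer_type")]))
    stop("driver catalog has more than one role for a (gene, cancer_type) pair")
  cat
}

#' Cross-tabulate RBPs against driver roles
#'
#' Partitions the RBPs found in a cancer-driver catalog into those with a
#' driver entry for the queried cancer type versus those with entries only
#' for other types, split by role. Each gene lands in exactly one cell, so
#' the cell counts sum to the size of the RBP-catalog intersection. A gene
#' with several other-type entries takes its highest-precedence role
#' (oncogene > tumor_suppressor > unknown).
#'
#' @param rbps Character vector (or `$genes`-bearing list) of RBP symbols.
#' @param catalog Driver-catalog data frame ([read_driver_catalog()]).
#' @param cancer_type Cancer-type label to treat as "in type".
#' @return 2 x 3 integer matrix, rows `in_type`/`other_type`, columns
#'   `oncogene`/`tumor_suppressor`/`unknown`.
#' @export
crosstab_roles <- function(rbps, catalog, cancer_type) {
  rbps <- as_gene_vector(rbps)
  catalog <- validate_driver_catalog(catalog)
  if (!cancer_type %in% catalog$cancer_type)
    stop("unknown cancer_type label: ", cancer_type)
  roles <- c("oncogene", "tumor_suppressor", "unknown")
  hit <- catalog[catalog$gene %in% rbps, , drop = FALSE]
  out <- matrix(0L, 2L, 3L,
                dimnames = list(c("in_type", "other_type"), roles))
  if (!nrow(hit)) return(out)
  for (g in unique(hit$gene)) {
    rows <- hit[hit$gene == g, , drop = FALSE]
    if (cancer_type %in% rows$cancer_type) {
      role <- rows$role[rows$cancer_type == cancer_type][1L]
      out["in_type", role] <- out["in_type", role] + 1L
    } else {
      role <- roles[min(match(rows$role, roles))]
      out["other_type", role] <- out["other_type", role] + 1L
    }
  }
  out
}
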