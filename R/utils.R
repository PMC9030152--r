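# Shared internal helpers and small exported utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Jaccard similarity between two gene sets
#'
#' @param a,b Character vectors of gene identifiers. Duplicates are ignored.
#' @return A number in \[0, 1\]; two empty sets have similarity 1.
#' @examples
#' jaccard(c("PUF60", "SF3A3"), c("PUF60", "TFRC"))
#' @export
jaccard <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) == 0L && length(b) == 0L) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# Derive a table-specific RNG seed from a master seed and a fixed label, so
# that adding one output table to the simulator never perturbs the others.
# Polynomial rolling hash mod (2^31 - 1), done in doubles to avoid overflow.
derive_seed <- function(seed, label) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% m
  as.integer(h)
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

# Accept either a character vector of genes or a list carrying $genes.
as_gene_vector <- function(x) {
  if (is.list(x) && !is.null(x$genes)) x <- x$genes
  unique(as.character(x))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}
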