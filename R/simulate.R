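# Synthetic-cohort generator with planted ground truth.
#
# Every input table the pipeline consumes can be generated here: per-sample
# alteration calls, sample annotations, ordinal IHC levels, two
# dependency-screen matrices with cell-line subtypes, a channel-tagged scored
# PPI edge list, a weighted functional network with a planted dense complex,
# a complex catalog, and the gene-set files. Planted progressor genes carry
# boosted amplification/mRNA-up rates, an upward IHC shift, strongly negative
# dependency scores, and a high-confidence PPI edge to a breast-cancer
# protein, so the four-criteria intersection has a known answer.

SIM_SUBTYPES <- c("Normal", "LumA", "LumB", "Her2", "Basal")
SIM_STAGES <- c("I", "II", "III", "IV")

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by the
#' `simulate_*` generators. Defaults describe a desk-scale cohort: 200
#' patients, a 280-gene universe (200 RBPs, 40 breast-cancer genes, 40
#' non-cancer genes), 5 planted progressor and 5 planted suppressor RBPs,
#' a 2% background alteration rate with a 10x boost on the
#' amplification/mRNA-up rates of planted progressors, 12 tumor IHC samples
#' per gene, two 30-cell-line screens with planted mean dependency score
#' -1.5 (noise SD 0.2), a 5% background edge probability for the functional
#' network, and a planted 12-gene complex.
#'
#' @param seed Integer master RNG seed. Each output table draws from its own
#'   stream derived from this seed, so generating one table never perturbs
#'   another.
#' @param n_patients Number of tumor samples in the alteration cohort.
#' @param set_sizes Named integer vector with elements `rbp`, `bc`,
#'   `noncancer`, `cdg`: sizes of the RBP, breast-cancer, non-cancer gene
#'   sets and of the cancer-driver catalog. The gene universe is the
#'   disjoint union of the first three.
#' @param n_planted_progressors,n_planted_suppressors Numbers of RBPs with
#'   planted progression (amplification + mRNA up) or suppression
#'   (deep deletion + mRNA down) profiles.
#' @param alteration_rate_background Per-(sample, gene) probability mass of
#'   an alteration event, split across categories by `category_weights`.
#' @param progressor_boost Multiplier applied to the amplification and
#'   mrna_up (resp. deep_deletion and mrna_down) per-category rates of
#'   planted progressors (resp. suppressors).
#' @param n_tumor_ihc_samples Tumor IHC samples scored per gene.
#' @param n_cell_lines Cell lines per dependency screen.
#' @param essential_mean Mean dependency score of planted essential genes
#'   (the planted progressors) in both screens; strongly negative means
#'   essential.
#' @param score_noise_sd Standard deviation of dependency-score noise.
#' @param noise_edge_prob Erdos-Renyi background edge probability of the
#'   functional network.
#' @param planted_complex_size Size of the planted clique (which contains
#'   all planted progressors).
#' @param subtype_props,stage_props Sampling proportions for sample subtype
#'   and stage annotations; must sum to 1.
#' @param subtype_rate_multipliers Per-subtype multiplier on the alteration
#'   rate, for planting subtype burden differences.
#' @param category_weights Relative frequency of each alteration category;
#'   must sum to 1. Defaults echo the category mix observed in breast
#'   tumors, where mRNA upregulation (~69%) and amplification (~15%)
#'   dominate.
#' @param ihc_noise_prob Probability that a background gene's tumor IHC
#'   sample shifts one ordinal level up (and, independently, down).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 200L,
                       set_sizes = c(rbp = 200L, bc = 40L, noncancer = 40L, cdg = 60L),
                       n_planted_progressors = 5L,
                       n_planted_suppressors = 5L,
                       alteration_rate_background = 0.02,
                       progressor_boost = 10,
                       n_tumor_ihc_samples = 12L,
                       n_cell_lines = 30L,
                       essential_mean = -1.5,
                       score_noise_sd = 0.2,
                       noise_edge_prob = 0.05,
                       planted_complex_size = 12L,
                       subtype_props = c(Normal = 0.2, LumA = 0.2, LumB = 0.2,
                                         Her2 = 0.2, Basal = 0.2),
                       stage_props = c(I = 0.25, II = 0.25, III = 0.25, IV = 0.25),
                       subtype_rate_multipliers = c(Normal = 1, LumA = 1, LumB = 1,
                                                    Her2 = 1, Basal = 1),
                       category_weights = c(mrna_up = 0.687, amplification = 0.154,
                                            mutation = 0.08, mrna_down = 0.04,
                                            deep_deletion = 0.025, fusion = 0.014),
                       ihc_noise_prob = 0.15) {
  cfg <- list(seed = as.integer(seed),
              n_patients = as.integer(n_patients),
              set_sizes = set_sizes,
              n_planted_progressors = as.integer(n_planted_progressors),
              n_planted_suppressors = as.integer(n_planted_suppressors),
              alteration_rate_background = alteration_rate_background,
              progressor_boost = progressor_boost,
              n_tumor_ihc_samples = as.integer(n_tumor_ihc_samples),
              n_cell_lines = as.integer(n_cell_lines),
              essential_mean = essential_mean,
              score_noise_sd = score_noise_sd,
              noise_edge_prob = noise_edge_prob,
              planted_complex_size = as.integer(planted_complex_size),
              subtype_props = subtype_props,
              stage_props = stage_props,
              subtype_rate_multipliers = subtype_rate_multipliers,
              category_weights = category_weights,
              ihc_noise_prob = ihc_noise_prob)
  validate_sim_config(cfg)
  cfg$n_genes <- sum(cfg$set_sizes[c("rbp", "bc", "noncancer")])
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  need <- c("rbp", "bc", "noncancer", "cdg")
  if (!all(need %in% names(cfg$set_sizes)))
    stop("configuration error: set_sizes must name rbp, bc, noncancer, cdg")
  counts <- c(cfg$n_patients, cfg$set_sizes, cfg$n_tumor_ihc_samples,
              cfg$n_cell_lines, cfg$planted_complex_size)
  if (any(counts <= 0)) stop("configuration error: all counts must be > 0")
  if (cfg$n_planted_progressors < 0 || cfg$n_planted_suppressors < 0)
    stop("configuration error: planted counts must be >= 0")
  probs <- c(cfg$alteration_rate_background, cfg$noise_edge_prob, cfg$ihc_noise_prob)
  if (any(probs < 0 | probs > 1))
    stop("configuration error: probabilities must lie in [0, 1]")
  if (cfg$score_noise_sd < 0) stop("configuration error: score_noise_sd must be >= 0")
  if (cfg$progressor_boost < 0) stop("configuration error: progressor_boost must be >= 0")
  if (cfg$n_planted_progressors + cfg$n_planted_suppressors > cfg$set_sizes[["rbp"]])
    stop("configuration error: planted genes exceed the RBP set size")
  if (cfg$planted_complex_size > cfg$set_sizes[["rbp"]])
    stop("configuration error: planted_complex_size exceeds the RBP set size")
  if (cfg$planted_complex_size < cfg$n_planted_progressors)
    stop("configuration error: planted complex must be able to contain the progressors")
  for (nm in c("subtype_props", "stage_props", "category_weights")) {
    p <- cfg[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
      stop(sprintf("configuration error: %s must be nonnegative and sum to 1", nm))
  }
  if (!setequal(names(cfg$subtype_props), SIM_SUBTYPES))
    stop("configuration error: subtype_props must name ", paste(SIM_SUBTYPES, collapse = ", "))
  if (!setequal(names(cfg$category_weights), ALTERATION_CATEGORIES))
    stop("configuration error: category_weights must name the six alteration categories")
  if (any(cfg$subtype_rate_multipliers < 0))
    stop("configuration error: subtype_rate_multipliers must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  seed %d; %d patients; %d genes (%d RBP / %d BC / %d non-cancer)\n",
              x$seed, x$n_patients, x$n_genes,
              x$set_sizes[["rbp"]], x$set_sizes[["bc"]], x$set_sizes[["noncancer"]]))
  cat(sprintf("  planted: %d progressors, %d suppressors, %d-gene complex\n",
              x$n_planted_progressors, x$n_planted_suppressors, x$planted_complex_size))
  cat(sprintf("  background alteration rate %.3g (boost %.3g); dependency mean %.2f (sd %.2f)\n",
              x$alteration_rate_background, x$progressor_boost,
              x$essential_mean, x$score_noise_sd))
  invisible(x)
}

#' Gene universe and planted ground truth
#'
#' Deterministically derives the simulated gene universe (disjoint RBP,
#' breast-cancer and non-cancer sets), the cancer-driver catalog, and the
#' planted gene sets from a configuration. All other generators share this
#' object, so the same config always plants the same genes.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_truth`: list with `genesets` (named list
#'   `rbp`, `bc`, `noncancer`), `catalog` (data frame gene/role/cancer_type),
#'   `planted_progressors`, `planted_suppressors`, `planted_complex`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "universe"), {
    sz <- config$set_sizes
    rbp <- sprintf("RBP%04d", seq_len(sz[["rbp"]]))
    bc <- sprintf("BC%03d", seq_len(sz[["bc"]]))
    noncancer <- sprintf("NC%03d", seq_len(sz[["noncancer"]]))

    prog <- sort(sample(rbp, config$n_planted_progressors))
    sup <- sort(sample(setdiff(rbp, prog), config$n_planted_suppressors))
    extra <- sample(setdiff(rbp, c(prog, sup)),
                    config$planted_complex_size - length(prog))
    complex_genes <- sort(c(prog, extra))

    # Catalog: every BC gene is a breast driver; remaining slots are RBPs
    # with driver roles in other cancer types.
    roles <- c("oncogene", "tumor_suppressor", "unknown")
    n_other <- max(0L, sz[["cdg"]] - length(bc))
    other_genes <- sample(rbp, min(n_other, length(rbp)))
    catalog <- data.frame(
      gene = c(bc, other_genes),
      role = c(sample(roles, length(bc), replace = TRUE, prob = c(0.25, 0.25, 0.5)),
               sample(roles, length(other_genes), replace = TRUE,
                      prob = c(0.15, 0.15, 0.7))),
      cancer_type = c(rep("breast", length(bc)), rep("other", length(other_genes))),
      stringsAsFactors = FALSE
    )

    structure(list(genesets = list(rbp = rbp, bc = bc, noncancer = noncancer),
                   catalog = catalog,
                   planted_progressors = prog,
                   planted_suppressors = sup,
                   planted_complex = complex_genes),
              class = "sim_truth")
  })
}

#' Simulate an alteration cohort
#'
#' Draws a long table of per-(sample, gene, category) alteration calls plus
#' subtype/stage sample annotations. Each (sample, gene, category) triple is
#' an independent Bernoulli draw with probability
#' `alteration_rate_background * category_weight * subtype_multiplier`,
#' boosted by `progressor_boost` on the amplification/mrna_up (progressors)
#' or deep_deletion/mrna_down (suppressors) categories of planted genes.
#'
#' @param config A [sim_config()].
#' @param truth Optional [simulate_truth()] result; derived from `config`
#'   when omitted.
#' @return List with `alterations` (data frame sample_id/gene/category),
#'   `samples` (data frame sample_id/subtype/stage), and `truth`.
#' @export
simulate_cohort <- function(config, truth = simulate_truth(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  genes <- unlist(truth$genesets, use.names = FALSE)
  G <- length(genes)
  n <- config$n_patients
  with_seed(derive_seed(config$seed, "cohort"), {
    samples <- data.frame(
      sample_id = sprintf("P%04d", seq_len(n)),
      subtype = sample(names(config$subtype_props), n, replace = TRUE,
                       prob = config$subtype_props),
      stage = sample(names(config$stage_props), n, replace = TRUE,
                     prob = config$stage_props),
      stringsAsFactors = FALSE
    )
    mult <- unname(config$subtype_rate_multipliers[samples$subtype])

    out <- vector("list", length(ALTERATION_CATEGORIES))
    for (i in seq_along(ALTERATION_CATEGORIES)) {
      cat_i <- ALTERATION_CATEGORIES[i]
      rate_g <- rep(config$alteration_rate_background *
                      config$category_weights[[cat_i]], G)
      names(rate_g) <- genes
      if (cat_i %in% c("amplification", "mrna_up"))
        rate_g[truth$planted_progressors] <-
          rate_g[truth$planted_progressors] * config$progressor_boost
      if (cat_i %in% c("deep_deletion", "mrna_down"))
        rate_g[truth$planted_suppressors] <-
          rate_g[truth$planted_suppressors] * config$progressor_boost
      # patients vary fastest: matrix of success probabilities n x G
      p <- pmin(1, outer(mult, rate_g))
      hit <- which(stats::rbinom(length(p), 1L, as.vector(p)) == 1L)
      if (length(hit)) {
        out[[i]] <- data.frame(
          sample_id = samples$sample_id[(hit - 1L) %% n + 1L],
          gene = genes[(hit - 1L) %/% n + 1L],
          category = cat_i,
          stringsAsFactors = FALSE
        )
      }
    }
    alterations <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(alterations))
      alterations <- data.frame(sample_id = character(), gene = character(),
                                category = character(), stringsAsFactors = FALSE)
    alterations <- alterations[order(alterations$sample_id, alterations$gene,
                                     alterations$category), , drop = FALSE]
    rownames(alterations) <- NULL
    list(alterations = alterations, samples = samples, truth = truth)
  })
}

#' Simulate immunohistochemistry levels
#'
#' For every RBP gene, draws one normal-tissue level and
#' `n_tumor_ihc_samples` tumor-sample levels on the 4-level ordinal scale
#' (not_detected < low < medium < high). Background genes jitter by at most
#' one level around their normal level; planted progressors shift up by 2-3
#' levels per tumor sample (and are seeded with a low normal level so the
#' shift is not clamped away), planted suppressors mirror this downward.
#'
#' @inheritParams simulate_cohort
#' @return Data frame with columns gene, tissue (`normal`/`tumor`),
#'   sample_id, level (ordinal label).
#' @export
simulate_ihc <- function(config, truth = simulate_truth(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  genes <- truth$genesets$rbp
  G <- length(genes)
  nt <- config$n_tumor_ihc_samples
  with_seed(derive_seed(config$seed, "ihc"), {
    normal <- sample(0:3, G, replace = TRUE, prob = c(0.2, 0.1, 0.5, 0.2))
    names(normal) <- genes
    normal[truth$planted_progressors] <-
      sample(0:1, length(truth$planted_progressors), replace = TRUE)
    normal[truth$planted_suppressors] <-
      sample(2:3, length(truth$planted_suppressors), replace = TRUE)

    p <- config$ihc_noise_prob
    shift <- matrix(sample(c(-1L, 0L, 1L), G * nt, replace = TRUE,
                           prob = c(p, 1 - 2 * p, p)),
                    nrow = G, dimnames = list(genes, NULL))
    if (length(truth$planted_progressors))
      shift[truth$planted_progressors, ] <-
        sample(c(2L, 3L), length(truth$planted_progressors) * nt,
               replace = TRUE, prob = c(0.7, 0.3))
    if (length(truth$planted_suppressors))
      shift[truth$planted_suppressors, ] <-
        -sample(c(2L, 3L), length(truth$planted_suppressors) * nt,
                replace = TRUE, prob = c(0.7, 0.3))
    tumor <- pmin(3L, pmax(0L, matrix(normal, G, nt) + shift))

    rbind(
      data.frame(gene = genes, tissue = "normal", sample_id = "N1",
                 level = ihc_level_label(normal), stringsAsFactors = FALSE),
      data.frame(gene = rep(genes, nt),
                 tissue = "tumor",
                 sample_id = rep(sprintf("T%02d", seq_len(nt)), each = G),
                 level = ihc_level_label(as.vector(tumor)),
                 stringsAsFactors = FALSE)
    )
  })
}

#' Simulate two loss-of-function dependency screens
#'
#' Background genes score Normal(0, `score_noise_sd`) in every cell line;
#' planted essential genes (the planted progressors) score
#' Normal(`essential_mean`, `score_noise_sd`) in both screens. Cell lines
#' carry molecular-subtype annotations.
#'
#' @inheritParams simulate_cohort
#' @return List with `rnai` and `crispr` (cell line x gene numeric
#'   matrices) and `cell_lines` (data frame cell_line/screen/subtype).
#' @export
simulate_dependency <- function(config, truth = simulate_truth(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  genes <- truth$genesets$rbp
  with_seed(derive_seed(config$seed, "dependency"), {
    draw_screen <- function(prefix) {
      nl <- config$n_cell_lines
      mu <- rep(0, length(genes))
      names(mu) <- genes
      mu[truth$planted_progressors] <- config$essential_mean
      m <- matrix(stats::rnorm(nl * length(genes),
                               mean = rep(mu, each = nl),
                               sd = config$score_noise_sd),
                  nrow = nl,
                  dimnames = list(sprintf("%s%02d", prefix, seq_len(nl)), genes))
      m
    }
    rnai <- draw_screen("RL")
    crispr <- draw_screen("CL")
    cell_lines <- data.frame(
      cell_line = c(rownames(rnai), rownames(crispr)),
      screen = rep(c("rnai", "crispr"), each = config$n_cell_lines),
      subtype = sample(SIM_SUBTYPES, 2L * config$n_cell_lines, replace = TRUE),
      stringsAsFactors = FALSE
    )
    list(rnai = rnai, crispr = crispr, cell_lines = cell_lines)
  })
}

#' Simulate PPI edges, the functional network and a complex catalog
#'
#' The scored PPI list gives every planted gene at least one
#' experimental-channel edge with score >= 0.9 to a breast-cancer protein;
#' background edges get Uniform(0.4, 0.95) scores on mixed channels. The
#' functional network is an Erdos-Renyi background at `noise_edge_prob` over
#' the whole gene universe plus a planted clique of `planted_complex_size`
#' RBPs (containing all planted progressors). The complex catalog holds the
#' planted complex under the name `"Spliceosome"` plus decoy complexes.
#'
#' @inheritParams simulate_cohort
#' @return List with `ppi` (data frame gene_a/gene_b/channel/score),
#'   `funcnet` (data frame gene_a/gene_b/weight), and `complexes` (named
#'   list of gene vectors).
#' @export
simulate_networks <- function(config, truth = simulate_truth(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  genes <- unlist(truth$genesets, use.names = FALSE)
  G <- length(genes)
  with_seed(derive_seed(config$seed, "networks"), {
    channels <- c("experimental", "database", "textmining", "coexpression", "other")

    planted <- c(truth$planted_progressors, truth$planted_suppressors)
    ppi_planted <- if (length(planted)) {
      data.frame(gene_a = planted,
                 gene_b = sample(truth$genesets$bc, length(planted), replace = TRUE),
                 channel = "experimental",
                 score = stats::runif(length(planted), 0.9, 0.999),
                 stringsAsFactors = FALSE)
    }
    n_bg <- 3L * G
    a <- sample(genes, n_bg, replace = TRUE)
    b <- sample(genes, n_bg, replace = TRUE)
    keep <- a != b
    ppi_bg <- data.frame(gene_a = a[keep], gene_b = b[keep],
                         channel = sample(channels, sum(keep), replace = TRUE),
                         score = stats::runif(sum(keep), 0.4, 0.95),
                         stringsAsFactors = FALSE)
    ppi <- rbind(ppi_planted, ppi_bg)
    swap <- ppi$gene_a > ppi$gene_b
    tmp <- ppi$gene_a[swap]
    ppi$gene_a[swap] <- ppi$gene_b[swap]
    ppi$gene_b[swap] <- tmp
    ppi <- ppi[!duplicated(ppi[c("gene_a", "gene_b", "channel")]), , drop = FALSE]
    ppi <- ppi[order(ppi$gene_a, ppi$gene_b, ppi$channel), , drop = FALSE]
    rownames(ppi) <- NULL

    # functional network: ER background plus planted clique
    pairs <- utils::combn(genes, 2L)
    on <- stats::rbinom(ncol(pairs), 1L, config$noise_edge_prob) == 1L
    funcnet <- data.frame(gene_a = pairs[1L, on], gene_b = pairs[2L, on],
                          stringsAsFactors = FALSE)
    cl <- truth$planted_complex
    if (length(cl) >= 2L) {
      cp <- utils::combn(sort(cl), 2L)
      funcnet <- rbind(funcnet,
                       data.frame(gene_a = cp[1L, ], gene_b = cp[2L, ],
                                  stringsAsFactors = FALSE))
    }
    funcnet <- funcnet[!duplicated(funcnet), , drop = FALSE]
    funcnet$weight <- stats::runif(nrow(funcnet), 0.5, 3)
    funcnet <- funcnet[order(funcnet$gene_a, funcnet$gene_b), , drop = FALSE]
    rownames(funcnet) <- NULL

    complexes <- c(list(Spliceosome = truth$planted_complex),
                   stats::setNames(
                     lapply(1:5, function(i) sort(sample(genes, 10L))),
                     sprintf("Decoy_complex_%d", 1:5)))
    list(ppi = ppi, funcnet = funcnet, complexes = complexes)
  })
}

#' Generate every pipeline input at once
#'
#' @inheritParams simulate_cohort
#' @return List with `truth`, `alterations`, `samples`, `ihc`, `dependency`
#'   (list rnai/crispr/cell_lines), `ppi`, `funcnet`, `complexes`.
#' @export
simulate_all <- function(config) {
  truth <- simulate_truth(config)
  cohort <- simulate_cohort(config, truth)
  dep <- simulate_dependency(config, truth)
  nets <- simulate_networks(config, truth)
  list(truth = truth,
       alterations = cohort$alterations,
       samples = cohort$samples,
       ihc = simulate_ihc(config, truth),
       dependency = dep,
       ppi = nets$ppi,
       funcnet = nets$funcnet,
       complexes = nets$complexes)
}

#' Write a simulated data set to disk
#'
#' Writes the TSV/GMT/JSON files a file-based pipeline run would read:
#' alterations.tsv, samples.tsv, ihc.tsv, dep_rnai.tsv, dep_crispr.tsv,
#' cell_lines.tsv, ppi.tsv, funcnet.tsv, complexes.gmt, genesets/*.gmt,
#' catalog.tsv and truth.json.
#'
#' @param sim Result of [simulate_all()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "genesets"), showWarnings = FALSE)
  write_tsv(sim$alterations, file.path(dir, "alterations.tsv"))
  write_tsv(sim$samples, file.path(dir, "samples.tsv"))
  write_tsv(sim$ihc, file.path(dir, "ihc.tsv"))
  for (screen in c("rnai", "crispr")) {
    m <- sim$dependency[[screen]]
    df <- data.frame(cell_line = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_tsv(df, file.path(dir, sprintf("dep_%s.tsv", screen)))
  }
  write_tsv(sim$dependency$cell_lines, file.path(dir, "cell_lines.tsv"))
  write_tsv(sim$ppi, file.path(dir, "ppi.tsv"))
  write_tsv(sim$funcnet, file.path(dir, "funcnet.tsv"))
  write_gmt(sim$complexes, file.path(dir, "complexes.gmt"))
  write_gmt(sim$truth$genesets, file.path(dir, "genesets", "genesets.gmt"))
  write_tsv(sim$truth$catalog, file.path(dir, "catalog.tsv"))
  jsonlite::write_json(
    list(planted_progressors = sim$truth$planted_progressors,
         planted_suppressors = sim$truth$planted_suppressors,
         planted_complex = sim$truth$planted_complex),
    file.path(dir, "truth.json"))
  invisible(dir)
}
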