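# Pipeline orchestration: a single run configuration drives
# simulate -> alterations -> ihc -> ppi -> dependency -> prioritize ->
# netcluster and yields a structured, serializable run report.

#' Pipeline run configuration
#'
#' @param seed Integer seed; also seeds the embedded simulation config
#'   unless one is supplied.
#' @param sim A [sim_config()] describing the synthetic inputs.
#' @param min_score PPI confidence threshold (inclusive).
#' @param channels PPI evidence channels to keep.
#' @param dep_threshold Dependency threshold magnitude.
#' @param mcode List of MCODE parameters: `node_score_cutoff`, `fluff`,
#'   `haircut`.
#' @param out Optional output directory; when set, all intermediate tables
#'   and the report are written there.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       sim = sim_config(seed = seed),
                       min_score = 0.9,
                       channels = c("experimental", "database"),
                       dep_threshold = 0.5,
                       mcode = list(node_score_cutoff = 0.1, fluff = 0,
                                    haircut = FALSE),
                       out = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  if (min_score < 0 || min_score > 1) stop("min_score must lie in [0, 1]")
  if (dep_threshold <= 0) stop("dep_threshold must be > 0")
  bad <- setdiff(channels, PPI_CHANNELS)
  if (length(bad)) stop("unknown PPI channel(s): ", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), sim = sim, min_score = min_score,
                 channels = channels, dep_threshold = dep_threshold,
                 mcode = mcode, out = out),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; the `sim` block
#' mirrors [sim_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1L
  sim_args <- y$sim %||% list()
  if (is.null(sim_args$seed)) sim_args$seed <- seed
  for (nm in c("set_sizes", "subtype_props", "stage_props",
               "subtype_rate_multipliers", "category_weights"))
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  sim <- do.call(sim_config, sim_args)
  run_config(seed = seed, sim = sim,
             min_score = y$min_score %||% 0.9,
             channels = y$channels %||% c("experimental", "database"),
             dep_threshold = y$dep_threshold %||% 0.5,
             mcode = utils::modifyList(list(node_score_cutoff = 0.1, fluff = 0,
                                            haircut = FALSE), y$mcode %||% list()),
             out = y$out)
}

#' Run the full prioritization pipeline
#'
#' Executes every stage on a synthetic cohort generated from the embedded
#' simulation config: alteration-burden profiling (progression and
#' suppression profiles, first-quartile selection, gene-set and
#' subtype/stage rank comparisons), IHC shift classification, PPI filtering
#' and bipartite extraction, essentiality calling on both screens, the
#' four-criteria intersection in both directions, and MCODE clustering of
#' the disease network seeded by the prioritized genes, annotated against
#' the complex catalog. Because the inputs carry planted ground truth, the
#' report also scores recovery (Jaccard of prioritized genes vs planted
#' progressors, and of the top complex vs the planted complex).
#'
#' @param config A [run_config()] (or a path to a YAML file for
#'   [read_run_config()]).
#' @param sim Optional pre-generated [simulate_all()] result (to rerun
#'   analysis stages on fixed inputs, e.g. with an emptied PPI table).
#' @return Object of class `run_report`: a nested list with `version`,
#'   `seed`, `stages` (row counts), `criteria`, `prioritized`, `near_miss`,
#'   `suppression`, `top_complex`, `recovery`, and `timestamp`. All fields
#'   except `timestamp` are deterministic for a fixed config.
#' @export
run_pipeline <- function(config, sim = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(sim)) sim <- simulate_all(config$sim)
  truth <- sim$truth
  rbp <- truth$genesets$rbp
  bc <- truth$genesets$bc
  noncancer <- truth$genesets$noncancer
  cdg <- unique(truth$catalog$gene)

  # --- alterations ---------------------------------------------------------
  counts_prog <- count_per_gene(sim$alterations, "progression", universe = rbp)
  counts_sup <- count_per_gene(sim$alterations, "suppression", universe = rbp)
  q_prog <- first_quartile_genes(counts_prog)
  q_sup <- first_quartile_genes(counts_sup)
  burden_rbp <- burden_per_patient(sim$alterations, rbp, sim$samples)
  burden_nc <- burden_per_patient(sim$alterations, noncancer, sim$samples)
  mw_rbp_vs_nc <- mann_whitney(burden_rbp, burden_nc)
  burden_subtype <- burden_by_group(sim$alterations, sim$samples, "subtype",
                                    geneset = rbp)
  burden_stage <- burden_by_group(sim$alterations, sim$samples, "stage",
                                  geneset = rbp)
  breakdown <- category_breakdown(sim$alterations, geneset = rbp)

  # --- ihc -----------------------------------------------------------------
  shifts <- ihc_shift_table(sim$ihc)
  c3_prog <- shifts$gene[overexpression_flag(shifts$delta)]
  c3_sup <- shifts$gene[shifts$delta <= -1L]

  # --- ppi -----------------------------------------------------------------
  filtered <- filter_edges(sim$ppi, allowed_channels = config$channels,
                           min_score = config$min_score)
  bipartite <- extract_bipartite(filtered, bc_set = bc, rbp_set = rbp)
  c2 <- names(bipartite$right_degree)[bipartite$right_degree >= 1L]

  # --- dependency ----------------------------------------------------------
  calls_rnai <- call_essential(sim$dependency$rnai,
                               threshold = config$dep_threshold, screen = "rnai")
  calls_crispr <- call_essential(sim$dependency$crispr,
                                 threshold = config$dep_threshold,
                                 screen = "crispr")
  screens <- combine_screens(calls_rnai, calls_crispr)
  crispr_ann <- sim$dependency$cell_lines[
    sim$dependency$cell_lines$screen == "crispr", , drop = FALSE]
  by_subtype <- essential_by_subtype(sim$dependency$crispr, crispr_ann,
                                     threshold = config$dep_threshold)

  # --- prioritize ----------------------------------------------------------
  ev_prog <- build_evidence(rbp, q_prog, c2, c3_prog, screens$union,
                            "progression")
  pr_prog <- prioritize_intersect(ev_prog)
  ev_sup <- build_evidence(rbp, q_sup, c2, c3_sup, screens$union,
                           "suppression")
  pr_sup <- prioritize_intersect(ev_sup)

  # --- netcluster ----------------------------------------------------------
  top_complex <- NULL
  if (length(pr_prog$prioritized)) {
    disease_net <- build_disease_network(sim$funcnet,
                                         seeds = pr_prog$prioritized,
                                         rbp_set = rbp, cdg_set = cdg)
    complexes <- mcode_find_complexes(
      disease_net,
      node_score_cutoff = config$mcode$node_score_cutoff,
      fluff = config$mcode$fluff,
      haircut = config$mcode$haircut)
    if (length(complexes)) {
      top <- complexes[[1L]]
      top_complex <- list(members = top$members, seed = top$seed,
                          score = top$score, n_edges = top$n_edges,
                          match = annotate_complex(top, sim$complexes))
    }
  }

  report <- structure(list(
    version = as.character(utils::packageVersion("rbpprio")),
    seed = config$seed,
    config = list(min_score = config$min_score, channels = config$channels,
                  dep_threshold = config$dep_threshold, mcode = config$mcode,
                  sim = unclass(config$sim)),
    stages = list(
      simulate = list(n_alterations = nrow(sim$alterations),
                      n_samples = nrow(sim$samples),
                      n_ihc_rows = nrow(sim$ihc),
                      n_ppi_edges = nrow(sim$ppi),
                      n_funcnet_edges = nrow(sim$funcnet)),
      alterations = list(n_rbp_genes = length(counts_prog),
                         burden_subtype = as.list(burden_subtype),
                         burden_stage = as.list(burden_stage),
                         category_breakdown = as.list(breakdown),
                         mw_rbp_vs_noncancer_p = mw_rbp_vs_nc$p_value),
      ihc = list(n_classified = nrow(shifts),
                 n_excluded = length(attr(shifts, "excluded"))),
      ppi = list(n_filtered_edges = nrow(filtered),
                 n_bc_connected = length(bipartite$left_degree),
                 n_rbp_connected = length(bipartite$right_degree)),
      dependency = list(n_essential_rnai = length(screens$rnai),
                        n_essential_crispr = length(screens$crispr),
                        n_essential_union = length(screens$union),
                        n_essential_intersection = length(screens$intersection),
                        essential_by_subtype = lapply(by_subtype$essential, length))),
    criteria = list(
      progression = list(c1 = length(q_prog), c2 = length(c2),
                         c3 = length(c3_prog), c4 = length(screens$union)),
      suppression = list(c1 = length(q_sup), c2 = length(c2),
                         c3 = length(c3_sup), c4 = length(screens$union))),
    prioritized = pr_prog$prioritized,
    near_miss = pr_prog$near_miss,
    venn_counts = as.list(pr_prog$venn_counts),
    suppression = list(prioritized = pr_sup$prioritized,
                       near_miss = pr_sup$near_miss),
    top_complex = top_complex,
    recovery = list(
      prioritized_jaccard = jaccard(pr_prog$prioritized,
                                    truth$planted_progressors),
      top_complex_jaccard = if (is.null(top_complex)) NA_real_ else
        jaccard(top_complex$members, truth$planted_complex)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_report")

  if (!is.null(config$out)) {
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    write_simulation(sim, file.path(config$out, "inputs"))
    write_tsv(data.frame(gene = names(counts_prog),
                         progression = as.integer(counts_prog),
                         suppression = as.integer(counts_sup)),
              file.path(config$out, "gene_counts.tsv"))
    write_tsv(shifts, file.path(config$out, "ihc_consensus.tsv"))
    write_tsv(filtered, file.path(config$out, "ppi_filtered.tsv"))
    write_tsv(rbind(calls_rnai, calls_crispr),
              file.path(config$out, "essentiality_calls.tsv"))
    write_tsv(ev_prog, file.path(config$out, "evidence_progression.tsv"))
    write_tsv(ev_sup, file.path(config$out, "evidence_suppression.tsv"))
    write_run_report(report, file.path(config$out, "report.json"))
    utils::capture.output(print(report),
                          file = file.path(config$out, "report.txt"))
  }
  report
}

#' Serialize a run report to JSON
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("rbpprio pipeline run (seed ", x$seed, ", version ", x$version, ")\n",
      sep = "")
  cat(sprintf("  alterations: %d events in %d samples\n",
              x$stages$simulate$n_alterations, x$stages$simulate$n_samples))
  cr <- x$criteria$progression
  cat(sprintf("  criteria (progression): quartile %d | PPI %d | IHC up %d | essential %d\n",
              cr$c1, cr$c2, cr$c3, cr$c4))
  cat(sprintf("  prioritized (%d): %s\n", length(x$prioritized),
              paste(x$prioritized, collapse = ", ")))
  cat(sprintf("  near-miss: %d genes\n", length(x$near_miss)))
  if (!is.null(x$top_complex))
    cat(sprintf("  top complex: %d nodes / %d edges, best match %s (%d matched, coverage %.2f)\n",
                length(x$top_complex$members), x$top_complex$n_edges,
                x$top_complex$match$catalog_name, x$top_complex$match$n_matched,
                x$top_complex$match$coverage))
  cat(sprintf("  recovery: prioritized Jaccard %.3f, top-complex Jaccard %.3f\n",
              x$recovery$prioritized_jaccard, x$recovery$top_complex_jaccard))
  invisible(x)
}
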