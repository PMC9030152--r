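# Synthetic-cohort generator: determinism, degenerate rates, planted
# effects, and label coherence.

test_that("identical configs give byte-identical outputs, table by table", {
  cfg <- sim_config(seed = 11)
  s1 <- simulate_all(cfg)
  s2 <- simulate_all(cfg)
  expect_identical(s1$alterations, s2$alterations)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$ihc, s2$ihc)
  expect_identical(s1$dependency, s2$dependency)
  expect_identical(s1$ppi, s2$ppi)
  expect_identical(s1$funcnet, s2$funcnet)
  expect_identical(s1$complexes, s2$complexes)
})

test_that("zero background alteration rate yields zero alteration rows", {
  cfg <- sim_config(seed = 3, alteration_rate_background = 0,
                    progressor_boost = 0)
  expect_equal(nrow(simulate_cohort(cfg)$alterations), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(subtype_props = c(Normal = 0.5, LumA = 0.5, LumB = 0.5,
                                            Her2 = 0.5, Basal = 0.5)),
               "sum to 1")
  expect_error(sim_config(alteration_rate_background = 1.5), "probabilities")
  expect_error(sim_config(n_planted_progressors = 300), "exceed")
  expect_error(sim_config(n_patients = 0), "counts")
})

test_that("planted progressors accumulate more events than background genes", {
  cfg <- sim_config(seed = 5, n_patients = 500)
  sim <- simulate_cohort(cfg)
  counts <- count_per_gene(sim$alterations, "progression",
                           universe = sim$truth$genesets$rbp)
  planted <- counts[sim$truth$planted_progressors]
  background <- counts[setdiff(names(counts),
                               c(sim$truth$planted_progressors,
                                 sim$truth$planted_suppressors))]
  expect_gt(mean(planted), mean(background))
  p <- stats::wilcox.test(planted, background, alternative = "greater",
                          exact = FALSE)$p.value
  expect_lt(p, 0.01)
})

test_that("raising progressor_boost does not lower the planted genes' rank", {
  ranks_at <- function(boost, seed) {
    cfg <- sim_config(seed = seed, progressor_boost = boost)
    sim <- simulate_cohort(cfg)
    counts <- count_per_gene(sim$alterations, "progression",
                             universe = sim$truth$genesets$rbp)
    mean(rank(counts)[sim$truth$planted_progressors])
  }
  for (seed in 1:5) {
    expect_gte(ranks_at(10, seed) + 5, ranks_at(1, seed))
  }
})

test_that("every generated gene id belongs to exactly one gene-set file", {
  cfg <- sim_config(seed = 9)
  sim <- simulate_all(cfg)
  sets <- sim$truth$genesets
  expect_equal(anyDuplicated(unlist(sets)), 0L)
  universe <- unlist(sets, use.names = FALSE)
  seen <- unique(c(sim$alterations$gene, sim$ihc$gene,
                   colnames(sim$dependency$rnai), colnames(sim$dependency$crispr),
                   sim$ppi$gene_a, sim$ppi$gene_b,
                   sim$funcnet$gene_a, sim$funcnet$gene_b,
                   unlist(sim$complexes), sim$truth$catalog$gene))
  expect_true(all(seen %in% universe))
  expect_true(all(sim$truth$planted_progressors %in% sets$rbp))
  expect_true(all(sim$truth$planted_suppressors %in% sets$rbp))
  expect_true(all(sim$truth$planted_complex %in% sets$rbp))
})

test_that("IHC: noiseless background genes keep their normal level in tumor", {
  cfg <- sim_config(seed = 2, ihc_noise_prob = 0)
  truth <- simulate_truth(cfg)
  ihc <- simulate_ihc(cfg, truth)
  shifts <- ihc_shift_table(ihc)
  background <- setdiff(shifts$gene, c(truth$planted_progressors,
                                       truth$planted_suppressors))
  expect_true(all(shifts$delta[shifts$gene %in% background] == 0L))
})

test_that("IHC: planted progressors shift up by at least two levels", {
  cfg <- sim_config(seed = 4)
  truth <- simulate_truth(cfg)
  shifts <- ihc_shift_table(simulate_ihc(cfg, truth))
  planted <- shifts[shifts$gene %in% truth$planted_progressors, ]
  expect_true(all(planted$delta >= 2L))
  expect_true(all(planted$class == "upregulated"))
  # a planted progressor starting at not_detected reaches at least medium
  nd <- planted[planted$normal == "not_detected", ]
  if (nrow(nd))
    expect_true(all(as_ihc_level(nd$tumor_consensus) >= 2L))
})

test_that("dependency screens: planted essentials are separated from nulls", {
  # null generator: essential_mean 0 flags (almost) nothing over many seeds
  flags <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = s, essential_mean = 0)
    truth <- simulate_truth(cfg)
    dep <- simulate_dependency(cfg, truth)
    calls <- call_essential(dep$crispr)
    mean(calls$essential[calls$gene %in% truth$planted_progressors])
  }, numeric(1))
  expect_lte(mean(flags), 0.01)

  # default planted mean -1.5, sd 0.2, 30 lines: all planted called
  cfg <- sim_config(seed = 1)
  truth <- simulate_truth(cfg)
  dep <- simulate_dependency(cfg, truth)
  for (screen in c("rnai", "crispr")) {
    calls <- call_essential(dep[[screen]])
    expect_true(all(calls$essential[calls$gene %in% truth$planted_progressors]))
  }
})

test_that("functional network honors noise and planting", {
  # no noise, no clique -> empty network
  cfg0 <- sim_config(seed = 6, noise_edge_prob = 0, planted_complex_size = 5,
                     n_planted_progressors = 5)
  truth0 <- simulate_truth(cfg0)
  truth0$planted_complex <- character(0)   # suppress the clique
  nets0 <- simulate_networks(cfg0, truth0)
  expect_equal(nrow(nets0$funcnet), 0L)

  # planted clique members have degree >= size - 1
  cfg <- sim_config(seed = 6)
  truth <- simulate_truth(cfg)
  nets <- simulate_networks(cfg, truth)
  deg <- table(c(nets$funcnet$gene_a, nets$funcnet$gene_b))
  expect_true(all(deg[truth$planted_complex] >= cfg$planted_complex_size - 1L))

  # catalog lookup of the planted complex returns exactly the planted set
  expect_setequal(nets$complexes$Spliceosome, truth$planted_complex)

  # every planted gene has a high-confidence experimental edge to a BC gene
  strong <- filter_edges(nets$ppi)
  strong_genes <- unique(c(strong$gene_a, strong$gene_b))
  expect_true(all(truth$planted_progressors %in% strong_genes))
})

test_that("write_simulation round-trips the main tables as plain text", {
  dir <- tempfile("simout")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  cfg <- sim_config(seed = 8, n_patients = 40)
  sim <- simulate_all(cfg)
  write_simulation(sim, dir)
  alts <- read.delim(file.path(dir, "alterations.tsv"), stringsAsFactors = FALSE)
  expect_equal(alts, sim$alterations, ignore_attr = TRUE)
  sets <- read_gmt(file.path(dir, "genesets", "genesets.gmt"))
  expect_setequal(sets$rbp, sim$truth$genesets$rbp)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_setequal(truth$planted_progressors, sim$truth$planted_progressors)
  dep <- read.delim(file.path(dir, "dep_crispr.tsv"), check.names = FALSE)
  expect_equal(dep$cell_line, rownames(sim$dependency$crispr))
})
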