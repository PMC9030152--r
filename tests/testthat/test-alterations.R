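# Alteration counting, burden normalization, rank comparisons and the
# first-quartile selection.

test_that("per-gene counts follow the profile category groups", {
  calls <- make_calls(list("s1", "g1", "amplification"),
                      list("s1", "g1", "mrna_up"),
                      list("s2", "g1", "deep_deletion"))
  expect_equal(count_per_gene(calls, "progression"), c(g1 = 2L))
  expect_equal(count_per_gene(calls, "suppression"), c(g1 = 1L))
  # a supplied universe reports zero-count genes
  expect_equal(count_per_gene(calls, "progression", universe = c("g1", "g2")),
               c(g1 = 2L, g2 = 0L))
  # empty input gives an all-zero map over the universe
  empty <- calls[0, ]
  expect_equal(count_per_gene(empty, "progression", universe = c("a", "b")),
               c(a = 0L, b = 0L))
})

test_that("fusion and mutation events count in both profiles", {
  calls <- make_calls(list("s1", "g1", "fusion"), list("s2", "g1", "mutation"))
  expect_equal(unname(count_per_gene(calls, "progression")), 2L)
  expect_equal(unname(count_per_gene(calls, "suppression")), 2L)
  # hence progression + suppression counts cover all categories at least once
  set.seed(1)
  rand <- data.frame(sample_id = sprintf("s%d", sample(5, 40, TRUE)),
                     gene = sprintf("g%d", sample(4, 40, TRUE)),
                     category = sample(ALTERATION_CATEGORIES, 40, TRUE),
                     stringsAsFactors = FALSE)
  u <- sprintf("g%d", 1:4)
  total <- count_per_gene(rand, profile_spec("progression"), u) +
    count_per_gene(rand, profile_spec("suppression"), u)
  all_cat <- table(factor(rand$gene, levels = u))
  expect_true(all(total >= as.integer(all_cat)))
})

test_that("unknown categories are rejected with the offending row", {
  calls <- make_calls(list("s1", "g1", "amplification"),
                      list("s2", "g2", "weird"))
  expect_error(count_per_gene(calls, "progression"), "weird.*row 2")
})

test_that("per-patient burden divides events by gene-set size", {
  calls <- make_calls(list("p1", "g1", "amplification"),
                      list("p1", "g1", "mutation"),
                      list("p1", "g2", "mrna_up"),
                      list("p1", "g2", "fusion"))
  expect_equal(burden_per_patient(calls, c("g1", "g2")), c(p1 = 2.0))
  # doubling the set with inert genes halves every burden
  doubled <- burden_per_patient(calls, c("g1", "g2", "x1", "x2"))
  expect_equal(unname(doubled), 1.0)
  # patients without events appear with burden zero when annotated
  samples <- data.frame(sample_id = c("p1", "p2"), subtype = "Basal",
                        stage = "I", stringsAsFactors = FALSE)
  b <- burden_per_patient(calls, c("g1", "g2"), samples)
  expect_equal(b[["p2"]], 0)
  expect_error(burden_per_patient(calls, character(0)), "empty geneset")
})

test_that("burden is invariant under row order and scales as 1/|geneset|", {
  set.seed(7)
  calls <- data.frame(sample_id = sprintf("p%d", sample(6, 60, TRUE)),
                      gene = sprintf("g%d", sample(8, 60, TRUE)),
                      category = sample(ALTERATION_CATEGORIES, 60, TRUE),
                      stringsAsFactors = FALSE)
  genes <- sprintf("g%d", 1:8)
  b1 <- burden_per_patient(calls, genes)
  b2 <- burden_per_patient(calls[sample(nrow(calls)), ], genes)
  expect_equal(b1, b2)
  widened <- burden_per_patient(calls, c(genes, sprintf("z%d", 1:8)))
  expect_equal(unname(widened), unname(b1) / 2)
})

test_that("group burden divides events by patients per group", {
  samples <- data.frame(sample_id = c("p1", "p2", "p3"),
                        subtype = c("Basal", "Basal", "LumA"),
                        stage = c("I", "I", "I"), stringsAsFactors = FALSE)
  calls <- make_calls(list("p1", "g1", "mutation"),
                      list("p2", "g1", "mutation"),
                      list("p2", "g2", "amplification"))
  b <- burden_by_group(calls, samples, "subtype")
  expect_equal(b, c(Basal = 1.5, LumA = 0))
  expect_false("Her2" %in% names(b))
  # single-group cohort: events / patients
  b2 <- burden_by_group(calls, samples, "stage")
  expect_equal(b2, c(I = 1))
})

test_that("a subtype with boosted event rate has the largest burden", {
  cfg <- sim_config(seed = 13, subtype_rate_multipliers =
                      c(Normal = 1, LumA = 1, LumB = 1, Her2 = 1, Basal = 3))
  sim <- simulate_cohort(cfg)
  b <- burden_by_group(sim$alterations, sim$samples, "subtype")
  expect_equal(names(which.max(b)), "Basal")
})

test_that("Mann-Whitney matches hand enumeration on the worked example", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_value, 2 * (1 / 6))
  expect_equal(r$method, "exact")
})

test_that("all-tied samples give the midpoint U and p = 1", {
  r <- mann_whitney(rep(2, 4), rep(2, 6))
  expect_equal(r$u_statistic, 4 * 6 / 2)
  expect_equal(r$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "empty sample")
})

test_that("U_x + U_y = n1 * n2 on random inputs", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(sample(2:12, 1))
    y <- rnorm(sample(2:12, 1))
    ux <- mann_whitney(x, y)$u_statistic
    uy <- mann_whitney(y, x)$u_statistic
    expect_equal(ux + uy, length(x) * length(y))
  }
})

test_that("exact branch equals brute-force enumeration for tie-free samples", {
  set.seed(11)
  for (n1 in 2:5) {
    for (n2 in 2:5) {
      x <- sample(seq_len(50), n1)
      y <- sample(setdiff(seq_len(50), x), n2)
      got <- mann_whitney(x, y)
      want <- oracle_mann_whitney(x, y)
      expect_equal(got$u_statistic, want$u)
      expect_equal(got$p_value, want$p)
    }
  }
})

test_that("normal-approximation branch agrees with the standard test", {
  set.seed(5)
  for (i in 1:10) {
    x <- sample(1:8, 15, replace = TRUE)   # ties on purpose
    y <- sample(2:9, 20, replace = TRUE)
    got <- mann_whitney(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(got$method, "normal_approx")
    expect_equal(got$u_statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("first-quartile selection uses interpolated percentiles with ties", {
  expect_equal(first_quartile_genes(c(a = 10, b = 8, c = 3, d = 1)), "a")
  expect_equal(first_quartile_genes(setNames(8:1, letters[1:8])), c("a", "b"))
  # degenerate distribution: everything ties the threshold
  expect_setequal(first_quartile_genes(c(x = 5, y = 5, z = 5)),
                  c("x", "y", "z"))
  # at least a quarter of the genes always selected
  set.seed(23)
  for (i in 1:20) {
    n <- sample(4:60, 1)
    counts <- setNames(rpois(n, 4), sprintf("g%d", seq_len(n)))
    expect_gte(length(first_quartile_genes(counts)), ceiling(n / 4))
  }
})

test_that("category breakdown gives event fractions over the vocabulary", {
  calls <- make_calls(
    list("s1", "g1", "mrna_up"), list("s2", "g1", "mrna_up"),
    list("s3", "g1", "mrna_up"), list("s4", "g1", "mrna_up"),
    list("s5", "g1", "mrna_up"), list("s6", "g1", "mrna_up"),
    list("s1", "g2", "amplification"), list("s2", "g2", "amplification"),
    list("s1", "g3", "mutation"), list("s2", "g3", "mutation"))
  f <- category_breakdown(calls)
  expect_equal(f[["mrna_up"]], 0.6)
  expect_equal(f[["amplification"]], 0.2)
  expect_equal(f[["mutation"]], 0.2)
  expect_equal(sum(f), 1)
  # single category
  f1 <- category_breakdown(calls[calls$category == "mutation", ])
  expect_equal(f1[["mutation"]], 1)
  expect_equal(sum(f1), 1)
  # empty input is flagged
  expect_warning(out <- category_breakdown(calls[0, ]), "empty")
  expect_length(out, 0)
})
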