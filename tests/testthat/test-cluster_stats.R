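# Minimal hand-rolled assignment builder for stats tests.
fake_assignment <- function(labels, k = max(labels)) {
  structure(list(labels = labels, k = as.integer(k),
                 centroids = NULL, sizes = tabulate(labels, nbins = k),
                 linkage_record = NULL, space = "expression"),
            class = "cluster_assignment")
}

test_that("cluster frequencies count and normalise per group", {
  labels <- c(1, 1, 2)
  meta <- data.frame(cell_id = c("a", "b", "c"), group = "day1")
  freq <- cluster_frequencies(fake_assignment(labels, 2), meta)
  expect_equal(freq$fraction, c(2 / 3, 1 / 3))
  expect_equal(freq$n_cells, c(2, 1))
  # multi-group: fractions sum to 1 and counts conserve group sizes
  set.seed(71)
  meta2 <- data.frame(cell_id = sprintf("c%03d", 1:120),
                      group = sample(c("littermate_control", "day3"), 120, TRUE))
  labels2 <- sample(1:4, 120, TRUE)
  freq2 <- cluster_frequencies(fake_assignment(labels2, 4), meta2)
  for (g in unique(meta2$group)) {
    sub <- freq2[freq2$group == g, ]
    expect_equal(sum(sub$fraction), 1, tolerance = 1e-12)
    expect_equal(sum(sub$n_cells), sum(meta2$group == g))
  }
  expect_error(cluster_frequencies(fake_assignment(labels, 2),
                                   data.frame(cell_id = c("a", "b", "c"),
                                              group = "weekX")),
               "unknown group")
})

test_that("the emergent cluster is the one that expands post-surgery", {
  freq <- rbind(
    data.frame(group = "littermate_control", cluster = 1:2,
               n_cells = c(99, 1), fraction = c(0.99, 0.01)),
    data.frame(group = "day3", cluster = 1:2,
               n_cells = c(60, 40), fraction = c(0.6, 0.4)))
  expect_equal(emergent_cluster(freq), 2L)
})

test_that("marker ranking matches a hand-computed one-vs-rest table", {
  x <- matrix(c(5, 6, 0, 1,    # gene gA: high in cluster 1
                1, 1, 4, 4,    # gene gB: high in cluster 2
                2, 2, 2, 2),   # gene gC: flat
              4, 3, dimnames = list(sprintf("c%d", 1:4), c("gA", "gB", "gC")))
  asn <- fake_assignment(c(1, 1, 2, 2))
  mk <- rank_markers(x, asn, top_n = 3)
  c1 <- mk[mk$cluster == 1, ]
  expect_equal(c1$gene, c("gA", "gC", "gB"))
  expect_equal(c1$log2fc, c(5.5 - 0.5, 0, 1 - 4))
  c2 <- mk[mk$cluster == 2, ]
  expect_equal(c2$gene[1], "gB")
  expect_equal(c2$log2fc[1], 3)
  # flat gene has zero fold change in both clusters
  expect_equal(mk$log2fc[mk$gene == "gC"], c(0, 0))
  # within a cluster, log2fc is non-increasing with rank and ranks unique
  for (c in 1:2) {
    sub <- mk[mk$cluster == c, ]
    expect_true(all(diff(sub$log2fc) <= 0))
    expect_equal(sub$rank, 1:3)
  }
})

test_that("marker ranking is invariant to cell order and defaults to 10 rows", {
  dp <- small_design()
  coh <- generate_cohort(dp$design, dp$programs, seed = 72)
  et <- ct_to_expression(coh$ct)
  asn <- cluster_cells(et, k = 3)
  mk <- rank_markers(et, asn)
  expect_equal(as.integer(table(mk$cluster)), rep(10L, 3))
  perm <- sample(nrow(et$et))
  x2 <- et$et[perm, ]
  asn2 <- fake_assignment(asn$labels[perm], 3)
  mk2 <- rank_markers(x2, asn2)
  expect_equal(mk, mk2)
  # tied fold changes break alphabetically
  xt <- matrix(c(1, 1, 0, 0, 1, 1, 0, 0), 4, 2,
               dimnames = list(NULL, c("zz", "aa")))
  mkt <- rank_markers(xt, fake_assignment(c(1, 1, 2, 2)), top_n = 2)
  expect_equal(mkt$gene[mkt$cluster == 1], c("aa", "zz"))
})

test_that("welch_test matches the closed-form Welch formulas", {
  welch_oracle <- function(a, b) {
    va <- var(a) / length(a); vb <- var(b) / length(b)
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    p <- 2 * stats::pt(-abs(t), df)
    list(t = t, df = df, p = p)
  }
  # the documented example pair
  a <- c(1, 2, 3); b <- c(4, 5, 6, 7)
  got <- welch_test(a, b)
  ora <- welch_oracle(a, b)
  expect_equal(got$t, ora$t, tolerance = 1e-10)
  expect_equal(got$df, ora$df, tolerance = 1e-10)
  expect_equal(got$p, ora$p, tolerance = 1e-10)
  # 100 random instances
  set.seed(73)
  for (i in 1:100) {
    a <- rnorm(sample(2:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    got <- welch_test(a, b)
    ora <- welch_oracle(a, b)
    expect_equal(got$t, ora$t, tolerance = 1e-10)
    expect_equal(got$df, ora$df, tolerance = 1e-10)
    expect_equal(got$p, ora$p, tolerance = 1e-10)
  }
})

test_that("welch_test degenerate conventions and star grading", {
  x <- c(2, 2, 2)
  res <- welch_test(x, c(2, 2))
  expect_equal(res$t, 0); expect_equal(res$p, 1); expect_equal(res$stars, "ns")
  res2 <- welch_test(x, c(5, 5))
  expect_equal(res2$p, 0)
  # identical samples with variance
  res3 <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res3$t, 0); expect_equal(res3$p, 1)
  expect_error(welch_test(1, c(1, 2)), ">= 2")
  expect_error(welch_test(c(1, NA, 2), c(1, 2)), "finite")
  # star thresholds: 0.05 / 0.01 / 0.001
  expect_equal(scqpcr:::star_grade(c(0.2, 0.04, 0.009, 0.0005)),
               c("ns", "*", "**", "***"))
})

test_that("pre/post comparison pools the first regenerative week against controls", {
  dp <- default_paper_design()
  coh <- generate_cohort(scale_design(dp$design, 300), dp$programs, seed = 74)
  et <- ct_to_expression(coh$ct)
  de <- prepost_comparison(et, genes = c("Vegfa", "Pecam1", "Tnf"))
  expect_equal(de$gene, c("Vegfa", "Pecam1", "Tnf"))
  expect_equal(nrow(de), 3)
  expect_true(all(de$p >= 0 & de$p <= 1))
  expect_true(all(de$stars %in% c("ns", "*", "**", "***")))
  expect_equal(de$display_log10_ctrl, log10(2) * de$mean_ctrl)
  # BH extension column is monotone-consistent with p
  expect_true(all(de$bh_q >= de$p - 1e-12))
  expect_error(prepost_comparison(et, genes = "NotAGene"), "not on panel")
})

test_that("type-I error of the pooled comparison is near nominal under the null", {
  # null genes: same program in every population
  n_genes <- 50
  panel <- sprintf("g%02d", seq_len(n_genes))
  sizes <- c(littermate_control = 60L, day1 = 40L, day3 = 40L, day7 = 40L)
  comp <- matrix(1, 4, 1, dimnames = list(names(sizes), NULL))
  bulk_design <- data.frame(cell_type = "t", source_pop = 1, replicates = 1)
  des <- study_design(sizes, comp, panel, panel[1:3], bulk_design)
  prog <- list(population_program(1, rep(5, n_genes), 1.5, 1))
  rejections <- 0; tests <- 0
  for (seed in 1:20) {
    et <- ct_to_expression(generate_cohort(des, prog, seed = seed)$ct)
    de <- prepost_comparison(et)
    rejections <- rejections + sum(de$p < 0.05)
    tests <- tests + nrow(de)
  }
  expect_lt(abs(rejections / tests - 0.05), 0.02)
})

test_that("a 2 log2-unit shift is detected with near-certain significance", {
  n_genes <- 10
  panel <- sprintf("g%02d", seq_len(n_genes))
  sizes <- c(littermate_control = 207L, day1 = 265L, day3 = 261L, day7 = 205L)
  comp <- matrix(0, 4, 2, dimnames = list(names(sizes), NULL))
  comp[1, 1] <- 1; comp[2:4, 2] <- 1
  bulk_design <- data.frame(cell_type = "t", source_pop = 1, replicates = 1)
  des <- study_design(sizes, comp, panel, panel[1:3], bulk_design)
  base <- rep(6, n_genes)
  programs <- list(population_program(1, base, 1.5, 1),
                   population_program(2, base + 2, 1.5, 1))
  stars <- vapply(1:20, function(seed) {
    et <- ct_to_expression(generate_cohort(des, programs, seed = seed)$ct)
    de <- prepost_comparison(et, genes = panel[1])
    de$stars
  }, character(1))
  expect_gte(mean(stars != "ns"), 0.95)
})

test_that("gene overlay scaling maps expression onto [0, 1]", {
  x <- matrix(c(0, 2, 4, 3, 3, 3), 3, 2, dimnames = list(NULL, c("gA", "gB")))
  expect_equal(unname(gene_overlay_scale(x, "gA")), c(0, 0.5, 1))
  expect_equal(unname(gene_overlay_scale(x, "gB")), c(0, 0, 0))
  set.seed(75)
  y <- cbind(v = rnorm(30))
  s <- gene_overlay_scale(y, "v")
  expect_equal(range(s), c(0, 1))
  expect_equal(order(s), order(y[, "v"]))
  expect_error(gene_overlay_scale(x, "gZ"), "not on panel")
})
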