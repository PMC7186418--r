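make_projection_fixture <- function(seed = 1, n_total = 200) {
  dp <- default_paper_design()
  design <- scale_design(dp$design, n_total)
  coh <- generate_cohort(design, dp$programs, seed = seed)
  et <- ct_to_expression(coh$ct)
  bk <- generate_bulk(design, dp$programs, noise_sd = 0.5, seed = seed + 1000)
  emb <- as_tsne_embedding(prcomp(et$et)$x[, 1:2])
  asn <- cluster_cells(et, k = 6)
  list(et = et, bulk = bk$bulk, bulk_truth = bk$truth, emb = emb, asn = asn,
       truth = coh$truth)
}

test_that("standardize_overlap z-scores each gene within each dataset", {
  fx <- make_projection_fixture(seed = 51)
  std <- standardize_overlap(fx$et, fx$bulk)
  for (mat in list(std$cells, std$bulk)) {
    expect_equal(unname(colMeans(mat)), rep(0, ncol(mat)), tolerance = 1e-12)
    expect_equal(unname(apply(mat, 2, sd)), rep(1, ncol(mat)), tolerance = 1e-12)
  }
  expect_identical(colnames(std$cells), colnames(std$bulk))
})

test_that("hand-computed z-scores match on a 3-gene toy", {
  x <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40, 5, 5, 7, 7), 4, 3,
              dimnames = list(sprintf("c%d", 1:4), c("gA", "gB", "gC")))
  bulk <- structure(list(samples = data.frame(sample_id = c("b1", "b2", "b3"),
                                              cell_type = "t"),
                         profiles = matrix(c(2, 4, 6, 1, 5, 9, 0, 1, 2), 3, 3,
                                           dimnames = list(c("b1", "b2", "b3"),
                                                           c("gA", "gB", "gC"))),
                         genes = c("gA", "gB", "gC")), class = "bulk_panel")
  std <- standardize_overlap(x, bulk, c("gA", "gB", "gC"))
  expect_equal(unname(std$cells[, "gA"]),
               (c(1, 2, 3, 4) - 2.5) / sd(c(1, 2, 3, 4)))
  expect_equal(unname(std$bulk[, "gB"]), (c(1, 5, 9) - 5) / 4)
})

test_that("genes constant in either dataset are dropped from both", {
  x <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 1, 1, 1, 1), 4, 3,
              dimnames = list(NULL, c("gA", "gB", "gC")))
  bulk <- structure(list(samples = data.frame(sample_id = c("b1", "b2"),
                                              cell_type = "t"),
                         profiles = matrix(c(2, 4, 3, 3, 5, 6), 2, 3,
                                           dimnames = list(c("b1", "b2"),
                                                           c("gA", "gB", "gC"))),
                         genes = c("gA", "gB", "gC")), class = "bulk_panel")
  # gB constant in bulk only; gC constant in cells only -> both dropped
  expect_error(standardize_overlap(x, bulk, c("gA", "gB", "gC")),
               "fewer than 3 usable overlap genes")
  x4 <- cbind(x, gD = c(2, 4, 6, 8), gE = c(1, 3, 2, 4))
  bulk$profiles <- cbind(bulk$profiles, gD = c(1, 7), gE = c(2, 9))
  bulk$genes <- colnames(bulk$profiles)
  std <- standardize_overlap(x4, bulk, bulk$genes)
  expect_identical(std$genes, c("gA", "gD", "gE"))
  expect_identical(std$dropped, c("gB", "gC"))
})

test_that("similarity entries are Pearson correlations over overlap genes", {
  fx <- make_projection_fixture(seed = 52)
  std <- standardize_overlap(fx$et, fx$bulk)
  sim <- similarity_matrix(std)
  expect_true(all(sim$values >= -1 - 1e-12 & sim$values <= 1 + 1e-12))
  # brute-force pairwise oracle on a corner of the matrix
  for (b in 1:3) for (c in 1:3)
    expect_equal(sim$values[b, c],
                 cor(std$bulk[b, ], std$cells[c, ]), tolerance = 1e-12)
})

test_that("bulk profiles copied from single cells match them at similarity 1", {
  # copying the whole cohort's overlap profiles into the bulk panel keeps the
  # per-gene z-transform identical in both datasets, so each copy correlates
  # with its source cell at exactly 1 and ranks it first for every m
  fx <- make_projection_fixture(seed = 53, n_total = 80)
  genes <- fx$bulk$genes
  profiles <- fx$et$et[, genes]
  ids <- sprintf("copy%03d_b01", seq_len(nrow(profiles)))
  rownames(profiles) <- ids
  bulk <- structure(list(samples = data.frame(sample_id = ids,
                                              cell_type = "copy"),
                         profiles = profiles, genes = genes),
                    class = "bulk_panel")
  std <- standardize_overlap(fx$et, bulk, genes)
  sim <- similarity_matrix(std)
  cells <- rownames(fx$et$et)
  for (i in c(1, 7, 40, 80))
    expect_equal(sim$values[ids[i], cells[i]], 1, tolerance = 1e-12)
  for (m in c(1, 5)) {
    proj <- match_and_project(sim, fx$emb, fx$asn, m = m)
    for (i in c(1, 7, 40)) {
      first <- proj$matches[proj$matches$bulk_sample == ids[i], ][1, ]
      expect_identical(first$matched_cell_id, cells[i])
      expect_equal(first$similarity, 1, tolerance = 1e-12)
      expect_equal(c(first$tsne1, first$tsne2),
                   unname(fx$emb$coords[cells[i], ]))
    }
  }
})

test_that("a negated z-profile yields similarity -1", {
  set.seed(54)
  x <- matrix(rnorm(40), 8, 5, dimnames = list(sprintf("c%d", 1:8),
                                               sprintf("g%d", 1:5)))
  zc <- scale(x)
  # the bulk panel of negated z-profiles has per-gene mean 0 / sd 1 itself,
  # so z-scoring reproduces it and each sample anti-correlates exactly
  profiles <- -zc
  rownames(profiles) <- sprintf("neg%d_b01", 1:8)
  bulk <- structure(list(samples = data.frame(sample_id = rownames(profiles),
                                              cell_type = "t"),
                         profiles = profiles, genes = colnames(x)),
                    class = "bulk_panel")
  std <- standardize_overlap(x, bulk, colnames(x))
  sim <- similarity_matrix(std)
  for (i in c(1, 3, 8))
    expect_equal(sim$values[sprintf("neg%d_b01", i), sprintf("c%d", i)], -1,
                 tolerance = 1e-10)
})

test_that("similarity is invariant to gene reordering and per-gene affine rescaling", {
  fx <- make_projection_fixture(seed = 55, n_total = 120)
  std <- standardize_overlap(fx$et, fx$bulk)
  sim <- similarity_matrix(std)$values
  # reorder genes
  perm <- sample(length(fx$bulk$genes))
  bulk2 <- fx$bulk
  bulk2$profiles <- bulk2$profiles[, perm]
  bulk2$genes <- colnames(bulk2$profiles)
  std2 <- standardize_overlap(fx$et, bulk2, bulk2$genes)
  expect_equal(similarity_matrix(std2)$values[, colnames(sim)], sim,
               tolerance = 1e-12)
  # rescale one gene within the bulk dataset
  bulk3 <- fx$bulk
  bulk3$profiles[, 4] <- bulk3$profiles[, 4] * 3 + 5
  std3 <- standardize_overlap(fx$et, bulk3, bulk3$genes)
  expect_equal(similarity_matrix(std3)$values, sim, tolerance = 1e-12)
})

test_that("synthetic bulk types project onto their source population's cluster", {
  agree <- 0; total <- 0
  for (seed in 1:20) {
    fx <- make_projection_fixture(seed = 60 + seed)
    std <- standardize_overlap(fx$et, fx$bulk)
    sim <- similarity_matrix(std)
    proj <- match_and_project(sim, fx$emb, fx$asn, m = 20)
    # dominant cluster of each population under the ground truth
    dom <- vapply(1:6, function(p) {
      cells <- names(fx$truth$population)[fx$truth$population == p]
      as.integer(names(which.max(table(fx$asn$labels[cells]))))
    }, integer(1))
    src_by_type <- tapply(fx$bulk_truth$source_pop, fx$bulk$samples$cell_type,
                          function(v) v[1])
    for (ct in names(proj$identity)) {
      total <- total + 1
      if (proj$identity[[ct]]$modal_cluster == dom[src_by_type[[ct]]])
        agree <- agree + 1
    }
  }
  expect_gte(agree / total, 0.9)
})

test_that("matched cells predominantly carry the source population's cluster", {
  fx <- make_projection_fixture(seed = 81)
  std <- standardize_overlap(fx$et, fx$bulk)
  sim <- similarity_matrix(std)
  proj <- match_and_project(sim, fx$emb, fx$asn, m = 20)
  dom <- vapply(1:6, function(p) {
    cells <- names(fx$truth$population)[fx$truth$population == p]
    as.integer(names(which.max(table(fx$asn$labels[cells]))))
  }, integer(1))
  src_by_type <- tapply(fx$bulk_truth$source_pop, fx$bulk$samples$cell_type,
                        function(v) v[1])
  hits <- mapply(function(cl, ct) cl == dom[src_by_type[[ct]]],
                 proj$matches$cluster, proj$matches$cell_type)
  expect_gte(mean(hits), 0.8)
  # distributions sum to one
  for (ct in names(proj$identity))
    expect_equal(sum(proj$identity[[ct]]$distribution), 1, tolerance = 1e-12)
})

test_that("co-clustering orders put identical rows adjacent and block structure contiguous", {
  set.seed(91)
  pattern <- seq(-1, 1, length.out = 6)
  vals <- rbind(matrix(pattern, 3, 6, byrow = TRUE),
                matrix(-pattern, 3, 6, byrow = TRUE))
  vals <- vals + matrix(rnorm(36, sd = 0.01), 6, 6)
  vals[2, ] <- vals[1, ]  # identical pair
  sim <- structure(list(values = vals, bulk_ids = sprintf("b%d", 1:6),
                        cell_ids = sprintf("c%d", 1:6), genes = letters[1:5]),
                   class = "similarity_matrix")
  ord <- cocluster_heatmap_order(sim)
  expect_setequal(ord$row_order, 1:6)
  expect_setequal(ord$col_order, 1:6)
  pos <- match(1:2, ord$row_order)
  expect_equal(abs(diff(pos)), 1)
  # the two blocks stay contiguous after ordering
  blocks <- rep(1:2, each = 3)[ord$row_order]
  expect_equal(length(rle(blocks)$lengths), 2)
})

test_that("empty or undersized inputs are rejected", {
  fx <- make_projection_fixture(seed = 82, n_total = 60)
  std <- standardize_overlap(fx$et, fx$bulk)
  sim <- similarity_matrix(std)
  expect_error(match_and_project(sim, fx$emb, fx$asn, m = 0), "m must be")
  expect_error(match_and_project(sim, fx$emb, fx$asn, m = 1e6), "m must be")
})
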