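#' Restrict and z-score single-cell and bulk profiles on the overlap genes
#'
#' Both datasets are restricted to `overlap_genes` in a canonical (given)
#' order, then each gene is standardized to mean 0 / sd 1 within its own
#' dataset, which absorbs platform-scale differences between single-cell and
#' bulk measurements. Genes constant in either dataset carry no similarity
#' information and are dropped from both (recorded in the result).
#'
#' @param et an `expression_matrix` or numeric matrix (cells x genes).
#' @param bulk a `bulk_panel`.
#' @param overlap_genes gene subset present in both inputs (>= 3 usable
#'   genes after dropping constants).
#' @return list with elements `cells` and `bulk` (z-scored matrices, genes
#'   in columns), `genes` (usable genes), `dropped` (constant genes).
#' @export
standardize_overlap <- function(et, bulk, overlap_genes = bulk$genes) {
  x <- as_et_matrix(et)
  stopifnot(inherits(bulk, "bulk_panel"))
  miss_sc <- setdiff(overlap_genes, colnames(x))
  fail_if(length(miss_sc) > 0L,
          "overlap gene absent from single-cell panel: ", paste(miss_sc, collapse = ", "))
  miss_bk <- setdiff(overlap_genes, colnames(bulk$profiles))
  fail_if(length(miss_bk) > 0L,
          "overlap gene absent from bulk panel: ", paste(miss_bk, collapse = ", "))
  sc <- x[, overlap_genes, drop = FALSE]
  bk <- bulk$profiles[, overlap_genes, drop = FALSE]
  const <- apply(sc, 2, sd) == 0 | apply(bk, 2, sd) == 0
  dropped <- overlap_genes[const]
  genes <- overlap_genes[!const]
  fail_if(length(genes) < 3,
          "fewer than 3 usable overlap genes after dropping constants")
  list(cells = scale(sc[, genes, drop = FALSE]),
       bulk = scale(bk[, genes, drop = FALSE]),
       genes = genes, dropped = dropped)
}

#' Bulk-to-cell similarity matrix
#'
#' Entry `(b, c)` is the Pearson correlation across the usable overlap genes
#' between bulk sample `b` and cell `c` (both z-scored per gene within
#' dataset by [standardize_overlap()]). Rows or columns with zero variance
#' across genes are excluded with a warning.
#'
#' @param std output of [standardize_overlap()].
#' @return an object of class `similarity_matrix` with elements `values`
#'   (n_bulk x n_cells, entries in `[-1, 1]`), `bulk_ids`, `cell_ids`,
#'   `genes`.
#' @export
similarity_matrix <- function(std) {
  bk <- std$bulk; sc <- std$cells
  var_b <- apply(bk, 1, sd) > 0
  var_c <- apply(sc, 1, sd) > 0
  if (any(!var_b)) warning("excluding zero-variance bulk sample(s): ",
                           paste(rownames(bk)[!var_b], collapse = ", "))
  if (any(!var_c)) warning("excluding zero-variance cell(s): ",
                           paste(rownames(sc)[!var_c], collapse = ", "))
  bk <- bk[var_b, , drop = FALSE]
  sc <- sc[var_c, , drop = FALSE]
  vals <- cor(t(bk), t(sc))
  structure(list(values = vals, bulk_ids = rownames(bk),
                 cell_ids = rownames(sc), genes = std$genes),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix: %d bulk samples x %d cells over %d genes\n",
              nrow(x$values), ncol(x$values), length(x$genes)))
  invisible(x)
}

#' Match bulk samples to cells and project them onto the map
#'
#' For each bulk sample the `m` highest-similarity cells (ties broken by
#' cell id order) define its projected dots on the 2-D map; one output row
#' per matched cell. Per bulk cell type, the distribution of matched cells
#' over clusters is reported together with the modal cluster — a
#' distribution rather than a single label, because a bulk population may
#' legitimately link to several clusters.
#'
#' @param sim a [similarity_matrix()].
#' @param embedding a `tsne_embedding` covering the similarity matrix cells.
#' @param assignment a `cluster_assignment` covering the same cells.
#' @param m matched cells per bulk sample (default 20).
#' @param cell_types optional named vector mapping bulk sample id to cell
#'   type; defaults to the prefix of the sample id before `"_b"`.
#' @return an object of class `bulk_projection` with elements `matches`
#'   (data frame: bulk_sample, cell_type, matched_cell_id, similarity,
#'   tsne1, tsne2, cluster) and `identity` (per cell type: modal cluster
#'   and cluster-distribution vector summing to 1).
#' @export
match_and_project <- function(sim, embedding, assignment, m = 20,
                              cell_types = NULL) {
  stopifnot(inherits(sim, "similarity_matrix"))
  n_cells <- ncol(sim$values)
  fail_if(n_cells == 0L || nrow(sim$values) == 0L, "empty similarity matrix")
  fail_if(m < 1 || m > n_cells, "m must be in 1..n_cells")
  coords <- embedding$coords[sim$cell_ids, , drop = FALSE]
  labels <- assignment$labels[sim$cell_ids]
  if (is.null(cell_types))
    cell_types <- stats::setNames(sub("_b[0-9]+$", "", sim$bulk_ids), sim$bulk_ids)
  rows <- vector("list", nrow(sim$values))
  for (b in seq_len(nrow(sim$values))) {
    s <- sim$values[b, ]
    top <- order(-s, sim$cell_ids)[seq_len(m)]
    rows[[b]] <- data.frame(
      bulk_sample = sim$bulk_ids[b],
      cell_type = unname(cell_types[sim$bulk_ids[b]]),
      matched_cell_id = sim$cell_ids[top],
      similarity = unname(s[top]),
      tsne1 = unname(coords[top, 1]), tsne2 = unname(coords[top, 2]),
      cluster = unname(labels[top]),
      stringsAsFactors = FALSE)
  }
  matches <- do.call(rbind, rows)
  k <- assignment$k
  identity <- lapply(split(matches$cluster, matches$cell_type), function(cl) {
    dist <- tabulate(cl, nbins = k) / length(cl)
    list(modal_cluster = which.max(dist), distribution = dist)
  })
  structure(list(matches = matches, identity = identity, m = m),
            class = "bulk_projection")
}

#' @export
print.bulk_projection <- function(x, ...) {
  cat(sprintf("bulk_projection: %d matched-cell dots (m = %d per bulk sample)\n",
              nrow(x$matches), x$m))
  for (ct in names(x$identity))
    cat(sprintf("  %s -> cluster %d (%.0f%% of matches)\n", ct,
                x$identity[[ct]]$modal_cluster,
                100 * max(x$identity[[ct]]$distribution)))
  invisible(x)
}

#' Row/column orderings for a co-clustered similarity heatmap
#'
#' Hierarchically clusters the bulk rows and the cell columns of the
#' similarity matrix (average linkage on correlation distance) and returns
#' the leaf orders, so similar samples and similar cells sit adjacently in
#' a heatmap export.
#'
#' @param sim a [similarity_matrix()].
#' @return list with integer permutations `row_order` and `col_order`.
#' @export
cocluster_heatmap_order <- function(sim) {
  stopifnot(inherits(sim, "similarity_matrix"))
  ord <- function(mat) {
    if (nrow(mat) < 3) return(seq_len(nrow(mat)))
    cc <- suppressWarnings(cor(t(mat)))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    hclust(stats::as.dist(1 - cc), method = "average")$order
  }
  list(row_order = ord(sim$values), col_order = ord(t(sim$values)))
}
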