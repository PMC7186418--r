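#' Density-dependent downsampling of cells
#'
#' Mirrors the density-aware downsampling stage of SPADE-style workflows:
#' local density is the number of neighboring cells within `kernel_radius`
#' (Euclidean on Et, excluding the cell itself, floored at 1 so isolated
#' cells are always retainable), and each cell is kept with probability
#' `min(1, c / density)` where `c` solves for an expected kept fraction of
#' `target_fraction`. Inverse-density sampling gives rare, low-density cells
#' retention probability 1 while thinning dense regions.
#'
#' @param et an `expression_matrix` or numeric matrix.
#' @param target_fraction expected fraction of cells to keep, in `(0, 1]`.
#' @param kernel_radius neighborhood radius in Et distance units.
#' @param seed integer seed for the Bernoulli keep draws.
#' @return integer vector of retained cell indices (increasing).
#' @export
density_downsample <- function(et, target_fraction, kernel_radius, seed = 1) {
  x <- as_et_matrix(et)
  n <- nrow(x)
  fail_if(!is.numeric(target_fraction) || target_fraction <= 0 || target_fraction > 1,
          "target_fraction must be in (0, 1]")
  fail_if(!is.numeric(kernel_radius) || kernel_radius <= 0,
          "kernel_radius must be positive")
  if (target_fraction >= 1) return(seq_len(n))
  d <- as.matrix(dist(x))
  density <- pmax(1, rowSums(d <= kernel_radius) - 1)
  # solve mean(pmin(1, c / density)) = target_fraction; monotone in c
  lo <- 0; hi <- max(density)
  for (step in 1:64) {
    mid <- (lo + hi) / 2
    if (mean(pmin(1, mid / density)) < target_fraction) lo <- mid else hi <- mid
  }
  keep_prob <- pmin(1, hi / density)
  set.seed(as.integer(seed %% 2147483647))
  which(runif(n) < keep_prob | keep_prob >= 1)
}

#' Cluster cells with k-constrained Ward agglomeration
#'
#' Agglomerative clustering (Ward linkage on Euclidean Et distances by
#' default) with the tree cut at exactly `k` clusters — the study's analysis
#' was constrained to a fixed cluster count (6). Optionally the tree is
#' built on a density-downsampled subset and held-out cells are assigned to
#' the nearest cut-cluster centroid. Clusters are relabeled 1..k by
#' decreasing size; reported centroids are within-cluster means over all
#' cells.
#'
#' @param et an `expression_matrix` or numeric matrix (cells x genes).
#' @param k number of clusters (default 6).
#' @param downsample optional list with elements `target_fraction`,
#'   `kernel_radius`, `seed` passed to [density_downsample()]; `NULL`
#'   (default) clusters all cells.
#' @param space `"expression"` (default; cluster in Et gene space, the
#'   SPADE convention) or `"embedding"` (cluster on 2-D map coordinates).
#' @param embedding a `tsne_embedding`, required when
#'   `space = "embedding"`.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"ward.D2"`, i.e. Ward on squared Euclidean distances).
#' @return an object of class `cluster_assignment` with elements `labels`
#'   (named integer vector in 1..k), `k`, `centroids` (k x n_genes),
#'   `sizes`, and `linkage_record` (the [stats::hclust()] merge history).
#' @export
cluster_cells <- function(et, k = 6, downsample = NULL,
                          space = c("expression", "embedding"),
                          embedding = NULL, linkage = "ward.D2") {
  space <- match.arg(space)
  x <- if (space == "embedding") {
    fail_if(is.null(embedding), "space = 'embedding' requires an embedding")
    embedding$coords
  } else {
    as_et_matrix(et)
  }
  n <- nrow(x)
  fail_if(n == 0L, "empty expression matrix")
  fail_if(k < 1, "k must be >= 1")
  fail_if(k > n, "k exceeds the number of cells")
  sub <- if (is.null(downsample)) seq_len(n) else
    density_downsample(x, downsample$target_fraction, downsample$kernel_radius,
                       downsample$seed %||% 1)
  fail_if(length(sub) < k, "downsampled set smaller than k")
  hc <- hclust(dist(x[sub, , drop = FALSE]), method = linkage)
  raw <- integer(n)
  raw[sub] <- cutree(hc, k = k)
  if (length(sub) < n) {
    cen <- t(vapply(seq_len(k), function(c)
      colMeans(x[sub[raw[sub] == c], , drop = FALSE]), numeric(ncol(x))))
    held <- setdiff(seq_len(n), sub)
    for (i in held) {
      d2 <- rowSums((cen - matrix(x[i, ], k, ncol(x), byrow = TRUE))^2)
      raw[i] <- which.min(d2)
    }
  }
  # relabel 1..k by decreasing size (ties: lower original label first)
  sizes <- tabulate(raw, nbins = k)
  ord <- order(-sizes, seq_len(k))
  labels <- match(raw, ord)
  names(labels) <- rownames(x)
  centroids <- t(vapply(seq_len(k), function(c) {
    colMeans(as_et_matrix(et)[labels == c, , drop = FALSE])
  }, numeric(ncol(as_et_matrix(et)))))
  rownames(centroids) <- seq_len(k)
  structure(list(labels = labels, k = as.integer(k), centroids = centroids,
                 sizes = tabulate(labels, nbins = k), linkage_record = hc,
                 space = space),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d cells in %d clusters (%s space)\n",
              length(x$labels), x$k, x$space))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Join cluster labels with embedding coordinates for map overlay
#'
#' @param assignment a `cluster_assignment`.
#' @param embedding a `tsne_embedding` over the same cells in the same order.
#' @return data frame with columns `cell_id`, `cluster`, `tsne1`, `tsne2`.
#' @export
overlay_labels <- function(assignment, embedding) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(embedding, "tsne_embedding"))
  fail_if(length(assignment$labels) != nrow(embedding$coords),
          "label/coordinate length mismatch")
  ids_a <- names(assignment$labels)
  ids_e <- rownames(embedding$coords)
  if (!is.null(ids_a) && !is.null(ids_e))
    fail_if(!identical(ids_a, ids_e), "cell ordering mismatch between labels and embedding")
  data.frame(cell_id = ids_a %||% seq_along(assignment$labels),
             cluster = unname(assignment$labels),
             tsne1 = unname(embedding$coords[, 1]),
             tsne2 = unname(embedding$coords[, 2]),
             stringsAsFactors = FALSE)
}
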