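#' Cluster frequencies per experimental group
#'
#' Counts cells per (group, cluster) and expresses each cluster as a
#' fraction of the cells in its group — the cluster-frequency time course.
#' Groups with zero cells are omitted; all `k` clusters are reported for
#' every present group (zero counts allowed), so fractions within a group
#' sum to 1.
#'
#' @param assignment a `cluster_assignment`.
#' @param meta per-cell metadata data frame with `cell_id` and `group`
#'   columns (e.g. `expression_matrix$meta`), same cells as the assignment.
#' @return data frame with columns `group`, `cluster`, `n_cells`,
#'   `fraction`, ordered by group (study order) then cluster.
#' @export
cluster_frequencies <- function(assignment, meta) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  fail_if(length(assignment$labels) != nrow(meta),
          "assignment does not cover the metadata cells")
  bad <- setdiff(unique(meta$group), GROUP_LEVELS)
  fail_if(length(bad) > 0L, "unknown group label: ", paste(bad, collapse = ", "))
  groups <- intersect(GROUP_LEVELS, unique(meta$group))
  k <- assignment$k
  out <- do.call(rbind, lapply(groups, function(g) {
    lab <- assignment$labels[meta$group == g]
    n <- tabulate(lab, nbins = k)
    data.frame(group = g, cluster = seq_len(k), n_cells = n,
               fraction = n / length(lab), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Identify the emergent cluster from a frequency table
#'
#' The emergent population is near-absent before surgery and prominent
#' after; operationally, the cluster maximizing (mean post-surgery
#' fraction) minus (mean control fraction).
#'
#' @param freq output of [cluster_frequencies()].
#' @return integer cluster id.
#' @export
emergent_cluster <- function(freq) {
  ctrl <- freq[freq$group %in% CONTROL_GROUPS, ]
  post <- freq[freq$group %in% POST_GROUPS, ]
  fail_if(nrow(ctrl) == 0L || nrow(post) == 0L,
          "need both control and post-surgery groups")
  gain <- tapply(post$fraction, post$cluster, mean) -
    tapply(ctrl$fraction, ctrl$cluster, mean)
  as.integer(names(gain)[which.max(gain)])
}

#' Rank marker genes per cluster by one-vs-rest log2 fold change
#'
#' For cluster `c` and gene `g`, `log2fc = mean(Et in c) - mean(Et in all
#' other clusters pooled)`. Et is log2-scale expression, so a difference of
#' means is a log2 fold change (delta-delta-Ct convention). Per cluster,
#' genes are sorted by decreasing log2fc (ties alphabetical) and the top
#' `top_n` retained.
#'
#' @param et an `expression_matrix` or numeric matrix.
#' @param assignment a `cluster_assignment` over the same cells.
#' @param top_n genes reported per cluster (default 10).
#' @return data frame with columns `cluster`, `rank`, `gene`, `log2fc`.
#' @export
rank_markers <- function(et, assignment, top_n = 10) {
  x <- as_et_matrix(et)
  stopifnot(inherits(assignment, "cluster_assignment"))
  fail_if(top_n > ncol(x), "top_n exceeds the number of genes")
  fail_if(assignment$k < 2, "need at least 2 clusters for one-vs-rest ranking")
  fail_if(any(assignment$sizes == 0L), "empty cluster")
  out <- do.call(rbind, lapply(seq_len(assignment$k), function(c) {
    inc <- assignment$labels == c
    fc <- colMeans(x[inc, , drop = FALSE]) - colMeans(x[!inc, , drop = FALSE])
    ord <- order(-fc, colnames(x))[seq_len(top_n)]
    data.frame(cluster = c, rank = seq_len(top_n), gene = colnames(x)[ord],
               log2fc = unname(fc[ord]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

star_grade <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Welch unequal-variance two-sample test
#'
#' Two-sided t-test for samples of unequal variances with
#' Welch-Satterthwaite degrees of freedom, graded with the conventional
#' significance stars (* p < 0.05, ** p < 0.01, *** p < 0.001). When both
#' samples have zero variance, p is 1 for equal means (no evidence of a
#' difference) and 0 for unequal means.
#'
#' @param a,b numeric vectors of expression values, each of length >= 2.
#' @return one-row data frame: `mean_a`, `mean_b`, `t`, `df`, `p`, `stars`.
#' @export
welch_test <- function(a, b) {
  fail_if(length(a) < 2 || length(b) < 2, "each sample needs >= 2 values")
  fail_if(any(!is.finite(a)) || any(!is.finite(b)), "values must be finite")
  if (var(a) == 0 && var(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    res <- data.frame(mean_a = mean(a), mean_b = mean(b),
                      t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                      df = length(a) + length(b) - 2,
                      p = if (eq) 1 else 0, stringsAsFactors = FALSE)
  } else {
    tt <- t.test(a, b, var.equal = FALSE)
    res <- data.frame(mean_a = mean(a), mean_b = mean(b),
                      t = unname(tt$statistic), df = unname(tt$parameter),
                      p = tt$p.value, stringsAsFactors = FALSE)
  }
  res$stars <- star_grade(res$p)
  res
}

#' Pre- vs post-surgery differential expression per gene
#'
#' Pool A is the littermate controls (optionally including the surgical
#' controls), pool B the post-surgery cells of days 1, 3 and 7 combined —
#' the first regenerative week. Each requested gene gets a [welch_test()]
#' row. A Benjamini-Hochberg adjusted q-value column (`bh_q`) is emitted as
#' a clearly-labeled extension; the per-gene stars themselves are
#' uncorrected, matching conventional violin-plot annotation. Display
#' columns on the log10 scale (`log10(2) * Et`) are included for violin
#' export; all statistics are computed on Et.
#'
#' @param et an `expression_matrix` (its `meta` supplies the groups).
#' @param genes gene subset to test; defaults to the full panel.
#' @param include_surgical include surgical controls in the control pool
#'   (default `FALSE`).
#' @return data frame: `gene`, `mean_ctrl`, `mean_pnx`, `t`, `df`, `p`,
#'   `stars`, `bh_q`, `display_log10_ctrl`, `display_log10_pnx`.
#' @export
prepost_comparison <- function(et, genes = NULL, include_surgical = FALSE) {
  stopifnot(inherits(et, "expression_matrix"))
  genes <- genes %||% et$panel
  miss <- setdiff(genes, et$panel)
  fail_if(length(miss) > 0L, "gene not on panel: ", paste(miss, collapse = ", "))
  ctrl_groups <- if (include_surgical) CONTROL_GROUPS else "littermate_control"
  in_ctrl <- et$meta$group %in% ctrl_groups
  in_pnx <- et$meta$group %in% POST_GROUPS
  fail_if(!any(in_ctrl), "empty control pool")
  fail_if(!any(in_pnx), "empty post-surgery pool")
  out <- do.call(rbind, lapply(genes, function(g) {
    res <- welch_test(et$et[in_ctrl, g], et$et[in_pnx, g])
    data.frame(gene = g, mean_ctrl = res$mean_a, mean_pnx = res$mean_b,
               t = res$t, df = res$df, p = res$p, stars = res$stars,
               stringsAsFactors = FALSE)
  }))
  out$bh_q <- p.adjust(out$p, method = "BH")
  out$display_log10_ctrl <- log10(2) * out$mean_ctrl
  out$display_log10_pnx <- log10(2) * out$mean_pnx
  rownames(out) <- NULL
  out
}

#' Min-max overlay scale for a gene across cells
#'
#' Rescales one gene's Et to `[0, 1]` for heat overlay on the 2-D map; a
#' constant gene maps to all zeros.
#'
#' @param et an `expression_matrix` or numeric matrix.
#' @param gene gene name on the panel.
#' @return named numeric vector of per-cell values in `[0, 1]`.
#' @export
gene_overlay_scale <- function(et, gene) {
  x <- as_et_matrix(et)
  fail_if(!(gene %in% colnames(x)), "gene not on panel: ", gene)
  v <- x[, gene]
  rng <- max(v) - min(v)
  if (rng == 0) return(stats::setNames(rep(0, length(v)), rownames(x)))
  stats::setNames((v - min(v)) / rng, rownames(x))
}
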