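#' Latent population expression program
#'
#' A population program specifies, for each gene on the panel, the mean and
#' standard deviation of expressed-cell Et (log2 units) and the probability
#' that a reaction yields signal at all. Detection is an independent Bernoulli
#' per reaction, layered on Gaussian Et noise — the simplest model that
#' reproduces the bimodal detect/non-detect structure of single-cell qPCR.
#'
#' @param pop_id integer population identifier.
#' @param mean_et per-gene mean Et (log2 units), all `>= 0`.
#' @param sd_et per-gene Et standard deviation, all `>= 0`; recycled.
#' @param detect_prob per-gene detection probability in `[0, 1]`; recycled.
#' @return an object of class `population_program`.
#' @export
population_program <- function(pop_id, mean_et, sd_et, detect_prob) {
  n <- length(mean_et)
  sd_et <- rep_len(sd_et, n)
  detect_prob <- rep_len(detect_prob, n)
  fail_if(any(mean_et < 0), "mean_et must be >= 0")
  fail_if(any(sd_et < 0), "sd_et must be >= 0")
  fail_if(any(detect_prob < 0 | detect_prob > 1), "detect_prob must be in [0, 1]")
  structure(list(pop_id = as.integer(pop_id), mean_et = mean_et,
                 sd_et = sd_et, detect_prob = detect_prob),
            class = "population_program")
}

#' Study design for synthetic cohort generation
#'
#' @param group_sizes named integer vector: cells per experimental group
#'   (names from the five study groups).
#' @param composition matrix `[n_groups x K]` of population mixing
#'   proportions; each row sums to 1; rownames are group names.
#' @param panel character vector of gene names.
#' @param overlap_genes subset of `panel` shared with the bulk reference.
#' @param bulk_design data frame with columns `cell_type`, `source_pop`,
#'   `replicates` describing the sorted-cell bulk panel.
#' @return an object of class `study_design`.
#' @export
study_design <- function(group_sizes, composition, panel, overlap_genes,
                         bulk_design) {
  fail_if(is.null(names(group_sizes)), "group_sizes must be named")
  bad <- setdiff(names(group_sizes), GROUP_LEVELS)
  fail_if(length(bad) > 0L, "unknown group in group_sizes: ", paste(bad, collapse = ", "))
  composition <- as.matrix(composition)
  fail_if(nrow(composition) != length(group_sizes),
          "composition must have one row per group")
  if (is.null(rownames(composition))) rownames(composition) <- names(group_sizes)
  fail_if(any(abs(rowSums(composition) - 1) > 1e-8),
          "each composition row must sum to 1")
  fail_if(any(composition < 0), "composition must be non-negative")
  miss <- setdiff(overlap_genes, panel)
  fail_if(length(miss) > 0L, "overlap gene absent from panel: ", paste(miss, collapse = ", "))
  bulk_design <- as.data.frame(bulk_design, stringsAsFactors = FALSE)
  need <- c("cell_type", "source_pop", "replicates")
  fail_if(!all(need %in% names(bulk_design)),
          "bulk_design needs columns cell_type, source_pop, replicates")
  structure(list(group_sizes = group_sizes, composition = composition,
                 panel = panel, overlap_genes = overlap_genes,
                 bulk_design = bulk_design),
            class = "study_design")
}

# Gene symbols printed in the study's figures and methods. The first 18 are
# the variable-expression overlap subset used for bulk matching.
OVERLAP_GENES_18 <- c("Col18a1", "Col4a3", "Csf3", "Ctgf", "Eng", "Ephb4",
                      "Ereg", "Fgf1", "Igf1", "Lep", "Mapk14", "Npr1",
                      "Pecam1", "S1pr1", "Sphk1", "Tgfa", "Tnf", "Vegfa")
FIGURE_GENES <- c("Acta2", "Eln", "Fbln1", "Fbln5", "Fbn1", "Flt1", "Flt4",
                  "Fn1", "Lox", "Ltbp2", "Ltbp4", "Mapk3", "Mmp14", "Mmp2",
                  "Pdgfra", "Pdgfrb", "Tgfb1")

#' Default study design emulating the post-pneumonectomy cohort
#'
#' Returns the study design and population programs used throughout the
#' package's verification: a 96-gene panel (the symbols printed in the study
#' plus synthetic placeholders), 1107 cells split 207/169/265/261/205 across
#' littermate-control / surgical-control / day-1 / day-3 / day-7 groups, six
#' latent populations, and a 73-sample bulk panel over 8 sorted cell types
#' sharing an 18-gene overlap subset. Population 2 is the emergent
#' population: frequency 0.005 in both control groups (surgical controls
#' share the littermate composition) and 0.24/0.30/0.27 on days 1/3/7
#' (mean 0.27).
#'
#' Each population expresses 3 of the 18 overlap genes plus 7 exclusive
#' panel genes at `separability` log2 cycles above background; six
#' housekeeping genes are expressed by every population. Expressed reactions
#' detect with probability `detect_expressed`, background reactions with
#' `detect_background`.
#'
#' @param separability marker effect size in log2 cycles (Et units) between
#'   a population's markers and background (default 6).
#' @param sd_et Gaussian Et noise standard deviation (default 1.5).
#' @param detect_expressed detection probability for expressed reactions.
#' @param detect_background detection probability for background reactions.
#' @return list with elements `design` (a [study_design()]) and `programs`
#'   (list of 6 [population_program()]s).
#' @export
default_paper_design <- function(separability = 6, sd_et = 1.5,
                                 detect_expressed = 0.92,
                                 detect_background = 0.08) {
  n_genes <- 96L
  named <- c(OVERLAP_GENES_18, FIGURE_GENES)
  panel <- c(named, sprintf("Syn%03d", seq_len(n_genes - length(named))))
  K <- 6L
  housekeeping <- c("Acta2", "Mapk3", "Syn059", "Syn060", "Syn061")
  # exclusive non-overlap markers, 7 per population
  pool <- setdiff(panel, c(OVERLAP_GENES_18, housekeeping))
  programs <- vector("list", K)
  for (p in seq_len(K)) {
    mean_et <- rep(0, n_genes)
    names(mean_et) <- panel
    markers <- c(OVERLAP_GENES_18[(3 * (p - 1) + 1):(3 * p)],
                 pool[(7 * (p - 1) + 1):(7 * p)])
    mean_et[markers] <- separability
    mean_et[housekeeping] <- 10
    detect <- ifelse(mean_et > 0, detect_expressed, detect_background)
    programs[[p]] <- population_program(p, unname(mean_et), sd_et, unname(detect))
  }
  group_sizes <- c(littermate_control = 207L, surgical_control = 169L,
                   day1 = 265L, day3 = 261L, day7 = 205L)
  ctrl <- c(0.32, 0.005, 0.27, 0.20, 0.12, 0.085)
  post <- function(f2) {
    rest <- ctrl[-2] / sum(ctrl[-2]) * (1 - f2)
    c(rest[1], f2, rest[2:5])
  }
  composition <- rbind(littermate_control = ctrl, surgical_control = ctrl,
                       day1 = post(0.24), day3 = post(0.30), day7 = post(0.27))
  bulk_design <- data.frame(
    cell_type = c("aSMA_myofibroblast", "TypeII_epithelial",
                  "CD34_endothelial_progenitor", "F480_alveolar_macrophage",
                  "CD11b_monocyte", "CD31_endothelial", "TypeI_epithelial",
                  "Lymphocyte"),
    source_pop = c(1L, 1L, 1L, 2L, 2L, 3L, 4L, 5L),
    replicates = c(10L, 9L, 9L, 9L, 9L, 9L, 9L, 9L),
    stringsAsFactors = FALSE)
  design <- study_design(group_sizes, composition, panel, OVERLAP_GENES_18,
                         bulk_design)
  list(design = design, programs = programs)
}

#' Scale a study design to a smaller total cell count
#'
#' Group sizes are scaled proportionally (largest-remainder rounding so the
#' total is exact); composition, panel and bulk design are unchanged.
#'
#' @param design a [study_design()].
#' @param n_total desired total cell count.
#' @return a [study_design()].
#' @export
scale_design <- function(design, n_total) {
  stopifnot(inherits(design, "study_design"))
  raw <- design$group_sizes / sum(design$group_sizes) * n_total
  sizes <- floor(raw)
  short <- n_total - sum(sizes)
  if (short > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[extra] <- sizes[extra] + 1L
  }
  out <- design
  out$group_sizes <- stats::setNames(as.integer(sizes), names(design$group_sizes))
  out
}

#' Generate a synthetic single-cell Ct cohort with ground truth
#'
#' For each cell, the latent population is drawn from its group's composition
#' vector; per gene, with probability `detect_prob` the reaction yields
#' `Ct = lod - Normal(mean_et, sd_et)` clamped to `(0, 40]` and rounded to
#' the instrument's two decimals, otherwise the reaction is censored. Draw
#' order is fixed (groups in study order; per group: population draws, then
#' the detection matrix, then the noise matrix), so output is bit-identical
#' for a given seed.
#'
#' @param design a [study_design()].
#' @param programs list of [population_program()]s covering every population
#'   referenced by the composition matrix.
#' @param seed integer seed.
#' @param lod limit-of-detection Ct used as the expression reference.
#' @return list with elements `ct` (a [ct_matrix()]) and `truth` (class
#'   `ground_truth`: per-cell population id, seed, design echo).
#' @export
generate_cohort <- function(design, programs, seed, lod = 24) {
  stopifnot(inherits(design, "study_design"))
  K <- ncol(design$composition)
  pop_ids <- vapply(programs, function(p) p$pop_id, integer(1))
  used <- which(colSums(design$composition) > 0)
  miss <- setdiff(used, pop_ids)
  fail_if(length(miss) > 0L,
          "composition references unknown population: ", paste(miss, collapse = ", "))
  n_genes <- length(design$panel)
  set.seed(as.integer(seed %% 2147483647))
  groups <- names(design$group_sizes)
  cell_group <- character(0)
  cell_pop <- integer(0)
  for (g in groups) {
    n <- design$group_sizes[[g]]
    if (n == 0) next
    pops <- sample.int(K, n, replace = TRUE, prob = design$composition[g, ])
    cell_group <- c(cell_group, rep(g, n))
    cell_pop <- c(cell_pop, pops)
  }
  n_cells <- length(cell_pop)
  idx <- match(cell_pop, pop_ids)
  mean_mat <- do.call(rbind, lapply(programs, function(p) p$mean_et))[idx, , drop = FALSE]
  sd_mat <- do.call(rbind, lapply(programs, function(p) p$sd_et))[idx, , drop = FALSE]
  det_mat <- do.call(rbind, lapply(programs, function(p) p$detect_prob))[idx, , drop = FALSE]
  detected <- matrix(runif(n_cells * n_genes), n_cells, n_genes) < det_mat
  et_draw <- matrix(rnorm(n_cells * n_genes), n_cells, n_genes) * sd_mat + mean_mat
  ct <- round(pmin(pmax(lod - et_draw, 0.01), 40), 2)
  ct[!detected] <- NA_real_
  counter <- stats::ave(seq_len(n_cells), cell_group, FUN = seq_along)
  meta <- data.frame(cell_id = sprintf("%s_c%04d", cell_group, counter),
                     group = cell_group, stringsAsFactors = FALSE)
  cm <- ct_matrix(ct, meta, panel = design$panel)
  truth <- structure(list(population = stats::setNames(cell_pop, meta$cell_id),
                          seed = as.integer(seed), design = design),
                     class = "ground_truth")
  list(ct = cm, truth = truth)
}

#' Generate a synthetic sorted-cell bulk panel
#'
#' Each bulk profile is its source population's mean Et restricted to the
#' overlap genes plus independent Gaussian noise; replicate counts follow
#' `design$bulk_design` (73 samples under the default design).
#'
#' @inheritParams generate_cohort
#' @param noise_sd bulk measurement noise in log2 units (default 0.5).
#' @return list with elements `bulk` (class `bulk_panel`: `samples` data
#'   frame, `profiles` matrix `[n_bulk x n_overlap]`, `genes`) and `truth`
#'   (per-sample source population).
#' @export
generate_bulk <- function(design, programs, noise_sd = 0.5, seed = 1) {
  stopifnot(inherits(design, "study_design"))
  fail_if(nrow(design$bulk_design) == 0L, "bulk_design is empty")
  miss <- setdiff(design$overlap_genes, design$panel)
  fail_if(length(miss) > 0L, "overlap gene absent from panel: ", paste(miss, collapse = ", "))
  pop_ids <- vapply(programs, function(p) p$pop_id, integer(1))
  gene_idx <- match(design$overlap_genes, design$panel)
  set.seed(as.integer(seed %% 2147483647))
  rows <- list(); ids <- character(0); types <- character(0); src <- integer(0)
  for (r in seq_len(nrow(design$bulk_design))) {
    bd <- design$bulk_design[r, ]
    prog <- programs[[match(bd$source_pop, pop_ids)]]
    fail_if(is.null(prog), "bulk source population not in programs: ", bd$source_pop)
    base <- prog$mean_et[gene_idx]
    for (rep_i in seq_len(bd$replicates)) {
      rows[[length(rows) + 1L]] <- pmax(base + rnorm(length(base), 0, noise_sd), 0)
      ids <- c(ids, sprintf("%s_b%02d", bd$cell_type, rep_i))
      types <- c(types, bd$cell_type)
      src <- c(src, bd$source_pop)
    }
  }
  profiles <- do.call(rbind, rows)
  dimnames(profiles) <- list(ids, design$overlap_genes)
  bulk <- structure(list(samples = data.frame(sample_id = ids, cell_type = types,
                                              stringsAsFactors = FALSE),
                         profiles = profiles, genes = design$overlap_genes),
                    class = "bulk_panel")
  truth <- structure(list(source_pop = stats::setNames(src, ids),
                          seed = as.integer(seed)),
                     class = "ground_truth")
  list(bulk = bulk, truth = truth)
}

#' @export
print.bulk_panel <- function(x, ...) {
  cat(sprintf("bulk_panel: %d sorted-cell samples x %d overlap genes (%d cell types)\n",
              nrow(x$profiles), length(x$genes), length(unique(x$samples$cell_type))))
  invisible(x)
}

#' Write a bulk panel to CSV (sample_id, cell_type, one column per gene)
#' @param x a `bulk_panel`.
#' @param path output path.
#' @export
write_bulk_panel <- function(x, path) {
  stopifnot(inherits(x, "bulk_panel"))
  out <- cbind(x$samples,
               as.data.frame(matrix(sprintf("%.4f", x$profiles), nrow(x$profiles),
                                    dimnames = dimnames(x$profiles)),
                             check.names = FALSE))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bulk panel written by [write_bulk_panel()]
#' @param path CSV path.
#' @export
load_bulk_panel <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  fail_if(!all(c("sample_id", "cell_type") %in% names(df)),
          "bulk CSV needs sample_id and cell_type columns")
  genes <- setdiff(names(df), c("sample_id", "cell_type"))
  profiles <- as.matrix(df[genes])
  dimnames(profiles) <- list(df$sample_id, genes)
  structure(list(samples = df[c("sample_id", "cell_type")],
                 profiles = profiles, genes = genes),
            class = "bulk_panel")
}

#' Write ground truth as JSON
#' @param truth a `ground_truth` object.
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  obj <- list(seed = truth$seed)
  if (!is.null(truth$population)) obj$population <- as.list(truth$population)
  if (!is.null(truth$source_pop)) obj$source_pop <- as.list(truth$source_pop)
  if (!is.null(truth$design)) {
    obj$design <- list(group_sizes = as.list(truth$design$group_sizes),
                       composition = unname(apply(truth$design$composition, 1, as.list)),
                       overlap_genes = truth$design$overlap_genes)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
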