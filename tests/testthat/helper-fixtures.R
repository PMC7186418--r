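# Small in-code fixtures shared across test files.

# A 3-cell x 2-gene Ct matrix with one censored reaction.
tiny_ct <- function() {
  ct <- matrix(c(20.00, 18.50, NA,
                 22.25, 24.00, 15.75), nrow = 3,
               dimnames = list(NULL, c("Vegfa", "Pecam1")))
  meta <- data.frame(cell_id = c("a", "b", "c"),
                     group = c("littermate_control", "day1", "day7"),
                     stringsAsFactors = FALSE)
  ct_matrix(ct, meta)
}

# Two well-separated Gaussian populations in gene space, with labels.
two_pop_matrix <- function(n_per = 20, n_genes = 10, shift = 8, sd = 0.5,
                           seed = 42) {
  set.seed(seed)
  x1 <- matrix(rnorm(n_per * n_genes, 0, sd), n_per, n_genes)
  x2 <- matrix(rnorm(n_per * n_genes, 0, sd), n_per, n_genes)
  x2[, 1:3] <- x2[, 1:3] + shift
  x <- abs(rbind(x1, x2))
  rownames(x) <- sprintf("cell%03d", seq_len(2 * n_per))
  colnames(x) <- sprintf("g%02d", seq_len(n_genes))
  list(x = x, labels = rep(1:2, each = n_per))
}

# A compact two-population study design for fast end-to-end runs.
small_design <- function(n_genes = 12, K = 3, sizes = c(littermate_control = 30L,
                                                        surgical_control = 20L,
                                                        day1 = 30L, day3 = 30L,
                                                        day7 = 30L)) {
  panel <- sprintf("g%02d", seq_len(n_genes))
  programs <- lapply(seq_len(K), function(p) {
    mean_et <- rep(0, n_genes)
    mean_et[((p - 1) * 3 + 1):(p * 3)] <- 7
    population_program(p, mean_et, 1, ifelse(mean_et > 0, 0.95, 0.05))
  })
  comp <- matrix(0, length(sizes), K, dimnames = list(names(sizes), NULL))
  comp[, seq_len(K)] <- 1 / K
  bulk_design <- data.frame(cell_type = sprintf("type%d", seq_len(K)),
                            source_pop = seq_len(K),
                            replicates = rep(2L, K), stringsAsFactors = FALSE)
  list(design = study_design(sizes, comp, panel, panel[1:6], bulk_design),
       programs = programs)
}

# Adjusted Rand index between two partitions (independent of the package).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Fraction of shared k-nearest neighbors between two embeddings.
knn_overlap <- function(y1, y2, k = 10) {
  d1 <- as.matrix(dist(y1)); d2 <- as.matrix(dist(y2))
  n <- nrow(d1)
  mean(vapply(seq_len(n), function(i) {
    n1 <- order(d1[i, ])[2:(k + 1)]
    n2 <- order(d2[i, ])[2:(k + 1)]
    length(intersect(n1, n2)) / k
  }, numeric(1)))
}

# Trustworthiness of an embedding w.r.t. the original space (standard
# definition; penalises points entering k-neighborhoods that are not
# high-dimensional neighbors).
trustworthiness <- function(x, y, k = 10) {
  n <- nrow(x)
  dx <- as.matrix(dist(x)); dy <- as.matrix(dist(y))
  total <- 0
  for (i in seq_len(n)) {
    rank_x <- order(order(dx[i, -i]))            # ranks among the other points
    names(rank_x) <- setdiff(seq_len(n), i)
    nn_y <- setdiff(order(dy[i, ]), i)[seq_len(k)]
    nn_x <- setdiff(order(dx[i, ]), i)[seq_len(k)]
    for (j in setdiff(nn_y, nn_x)) {
      total <- total + (rank_x[[as.character(j)]] - k)
    }
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * total
}
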