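#' t-SNE parameters
#'
#' Defaults mirror the study's stated run configuration (2000 iterations,
#' perplexity 10, Barnes-Hut accuracy theta 0.5) with the canonical published
#' optimization schedule for the quantities the study leaves unstated:
#' learning rate 200, early exaggeration 12 for the first 250 iterations,
#' momentum 0.5 switching to 0.8 at iteration 250.
#'
#' @param iterations total gradient-descent iterations.
#' @param perplexity target effective-neighbor count (`2^H`); must be below
#'   `n_cells / 3`.
#' @param theta Barnes-Hut accuracy in `[0, 1]`; `0` forces the exact
#'   O(n^2) gradient.
#' @param seed integer seed for the Gaussian initialization.
#' @param learning_rate positive gradient step scale.
#' @param early_exaggeration affinity inflation factor during the early phase.
#' @param exaggeration_iter length of the early-exaggeration phase.
#' @param momentum,final_momentum,momentum_switch momentum schedule.
#' @param record_every KL-trace checkpoint interval, in iterations.
#' @return an object of class `tsne_params`.
#' @export
tsne_params <- function(iterations = 2000, perplexity = 10, theta = 0.5,
                        seed = 1, learning_rate = 200,
                        early_exaggeration = 12, exaggeration_iter = 250,
                        momentum = 0.5, final_momentum = 0.8,
                        momentum_switch = 250, record_every = 50) {
  fail_if(iterations < 1, "iterations must be >= 1")
  fail_if(perplexity <= 1, "perplexity must be > 1")
  fail_if(theta < 0 || theta > 1, "theta must be in [0, 1]")
  fail_if(learning_rate <= 0, "learning_rate must be positive")
  structure(list(iterations = as.integer(iterations), perplexity = perplexity,
                 theta = theta, seed = as.integer(seed),
                 learning_rate = learning_rate,
                 early_exaggeration = early_exaggeration,
                 exaggeration_iter = as.integer(exaggeration_iter),
                 momentum = momentum, final_momentum = final_momentum,
                 momentum_switch = as.integer(momentum_switch),
                 record_every = as.integer(record_every)),
            class = "tsne_params")
}

as_et_matrix <- function(et) {
  if (inherits(et, "expression_matrix")) et$et else as.matrix(et)
}

# Deterministically jitter duplicated rows so the per-row bandwidth search
# cannot degenerate. The same offset is added to every gene of a duplicate
# row, preserving equivariance under gene reordering.
jitter_duplicates <- function(x) {
  dup <- which(duplicated(x))
  if (length(dup)) x[dup, ] <- x[dup, ] + 1e-8 * seq_along(dup)
  x
}

#' Per-cell conditional neighbor affinities at a target perplexity
#'
#' For each cell i, a Gaussian kernel bandwidth `sigma_i` is found by binary
#' search so that the Shannon perplexity `2^H(p_.|i)` of the conditional
#' distribution over the other cells matches the target within `tol`. Rows
#' sum to 1; the diagonal is 0.
#'
#' @param et an `expression_matrix` or numeric matrix (cells x genes).
#' @param perplexity target perplexity (effective neighbor count).
#' @param tol convergence tolerance on the achieved perplexity.
#' @param max_steps bound on the binary-search steps per row.
#' @return n x n row-stochastic matrix of conditional affinities.
#' @export
conditional_affinities <- function(et, perplexity, tol = 1e-4,
                                   max_steps = 200L) {
  x <- jitter_duplicates(as_et_matrix(et))
  n <- nrow(x)
  fail_if(n < 4, "need at least 4 cells")
  fail_if(perplexity >= n - 1,
          "perplexity must be below n_cells - 1, the uniform-distribution maximum")
  d2 <- as.matrix(dist(x))^2
  target <- log(perplexity)
  P <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1; beta_lo <- -Inf; beta_hi <- Inf
    ok <- FALSE
    for (step in seq_len(max_steps)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < .Machine$double.xmin) { # bandwidth too small: widen
        beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
        next
      }
      p <- w / sw
      # Shannon entropy in nats: H = log(sum w) + beta * E[d2]
      h <- log(sw) + beta * sum(di * w) / sw
      diff <- h - target
      if (abs(exp(h) - perplexity) < tol) { ok <- TRUE; break }
      if (diff > 0) { # too many effective neighbors: narrow the kernel
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    fail_if(!ok, sprintf("perplexity calibration did not converge for row %d", i))
    P[i, -i] <- p
  }
  P
}

#' Symmetrize conditional affinities into a joint distribution
#'
#' `p_ij = (p_(j|i) + p_(i|j)) / (2n)`; the result is symmetric and its
#' entries sum to 1.
#'
#' @param conditional square row-stochastic matrix from
#'   [conditional_affinities()].
#' @return symmetric joint affinity matrix.
#' @export
symmetrize_affinities <- function(conditional) {
  n <- nrow(conditional)
  fail_if(n != ncol(conditional), "conditional affinity matrix must be square")
  (conditional + t(conditional)) / (2 * n)
}

#' Embed an expression matrix in two dimensions with t-SNE
#'
#' Minimizes the Kullback-Leibler divergence between the joint
#' high-dimensional affinities (Gaussian kernels calibrated per cell to the
#' target perplexity, then symmetrized) and a Student-t kernel on the 2-D
#' coordinates, by momentum gradient descent with early exaggeration and
#' adaptive per-coordinate gains. Distances are Euclidean on Et over all
#' panel genes. `theta = 0` runs the exact gradient; `theta > 0` uses a
#' Barnes-Hut quadtree for the repulsive term. Coordinates are initialized
#' from a seeded Gaussian (sd 1e-4), so runs are deterministic given
#' `params$seed`.
#'
#' @param et an `expression_matrix` or numeric matrix (cells x genes).
#' @param params a [tsne_params()] object.
#' @return an object of class `tsne_embedding` with elements `coords`
#'   (n x 2, rownames = cell ids), `kl_trace` (data frame: iteration, kl;
#'   KL is always reported on the unexaggerated affinities), and `params`.
#' @export
tsne_embed <- function(et, params = tsne_params()) {
  x <- as_et_matrix(et)
  n <- nrow(x)
  fail_if(n < 10, "need at least 10 cells to embed")
  fail_if(params$perplexity >= n / 3, "perplexity must be < n_cells / 3")
  P <- symmetrize_affinities(conditional_affinities(x, params$perplexity))
  P <- pmax(P, .Machine$double.xmin) # floor so KL terms stay finite
  diag(P) <- 0
  set.seed(params$seed)
  y0 <- matrix(rnorm(2 * n, sd = 1e-4), n, 2)
  res <- tsne_gradient_cpp(P, y0, params$iterations, params$theta,
                           params$learning_rate, params$early_exaggeration,
                           params$exaggeration_iter, params$momentum,
                           params$final_momentum, params$momentum_switch,
                           params$record_every)
  coords <- res$Y
  dimnames(coords) <- list(rownames(x), c("tsne1", "tsne2"))
  fail_if(any(!is.finite(coords)), "non-finite embedding coordinates")
  structure(list(coords = coords,
                 kl_trace = data.frame(iteration = res$trace_iteration,
                                       kl = res$trace_kl),
                 params = params),
            class = "tsne_embedding")
}

#' Construct a `tsne_embedding` from precomputed coordinates
#'
#' Useful for overlaying labels or projecting bulk samples onto coordinates
#' obtained elsewhere (or onto a cheap stand-in such as principal
#' components during testing).
#'
#' @param coords n x 2 matrix with cell ids as rownames.
#' @param params optional parameter echo.
#' @export
as_tsne_embedding <- function(coords, params = NULL) {
  coords <- as.matrix(coords)
  fail_if(ncol(coords) != 2, "coords must have two columns")
  colnames(coords) <- c("tsne1", "tsne2")
  structure(list(coords = coords, kl_trace = data.frame(iteration = integer(0),
                                                        kl = numeric(0)),
                 params = params),
            class = "tsne_embedding")
}

#' @export
print.tsne_embedding <- function(x, ...) {
  cat(sprintf("tsne_embedding: %d cells in 2-D\n", nrow(x$coords)))
  if (nrow(x$kl_trace)) {
    last <- x$kl_trace[nrow(x$kl_trace), ]
    cat(sprintf("  final KL divergence %.4f at iteration %d\n", last$kl, last$iteration))
  }
  invisible(x)
}

#' Plot a t-SNE embedding, optionally colored by labels
#' @param x a `tsne_embedding`.
#' @param labels optional per-cell factor (e.g. cluster labels) for coloring.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tsne_embedding <- function(x, labels = NULL, ...) {
  col <- if (is.null(labels)) "grey30" else
    grDevices::hcl.colors(length(unique(labels)), "Dark 3")[as.integer(factor(labels))]
  graphics::plot(x$coords, col = col, pch = 16, cex = 0.6,
                 xlab = "tSNE 1", ylab = "tSNE 2", ...)
  invisible(x)
}
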