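#' Convert Ct values to LOD-referenced log2 expression (Et)
#'
#' Expression is measured in PCR cycles below the limit of detection:
#' `Et = max(0, lod - Ct)`. One cycle is one doubling, so Et is on a log2
#' scale. Censored (non-detected) reactions and reactions at or beyond the
#' LOD map to 0. The transform is monotone decreasing in Ct, so any
#' distance-based downstream stage is unaffected by the (affine) choice of
#' reference.
#'
#' @param ct a [ct_matrix()].
#' @param lod limit-of-detection Ct in cycles, in `(0, 40]` (default 24).
#' @return an object of class `expression_matrix` with elements `et` (matrix,
#'   all values `>= 0`), `meta`, `panel`, `lod`.
#' @export
ct_to_expression <- function(ct, lod = 24) {
  stopifnot(inherits(ct, "ct_matrix"))
  fail_if(!is.numeric(lod) || length(lod) != 1L || lod <= 0 || lod > 40,
          "lod must be a single value in (0, 40]")
  et <- pmax(lod - ct$ct, 0)
  et[is.na(et)] <- 0
  structure(list(et = et, meta = ct$meta, panel = ct$panel, lod = lod),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d genes (Et, log2 units; LOD = %g cycles)\n",
              nrow(x$et), length(x$panel), x$lod))
  cat(sprintf("  detected (Et > 0): %.1f%% of reactions\n", 100 * mean(x$et > 0)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$et)

#' Filter cells by number of detected genes
#'
#' Retains cells with at least `min_detected` non-censored reactions, in the
#' original order. May return an empty matrix; downstream stages reject empty
#' input themselves.
#'
#' @param ct a [ct_matrix()].
#' @param min_detected minimum number of detected (non-sentinel) genes.
#' @return a filtered [ct_matrix()].
#' @export
qc_filter <- function(ct, min_detected) {
  stopifnot(inherits(ct, "ct_matrix"))
  fail_if(!is.numeric(min_detected) || min_detected < 0,
          "min_detected must be >= 0")
  keep <- rowSums(!is.na(ct$ct)) >= min_detected
  out <- ct
  out$ct <- ct$ct[keep, , drop = FALSE]
  out$meta <- ct$meta[keep, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}
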