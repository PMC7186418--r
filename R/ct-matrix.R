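#' Ct matrix container
#'
#' A `ct_matrix` holds single-cell qPCR cycle-threshold (Ct) values together
#' with per-cell metadata. Valid Ct values lie in `(0, 40]` PCR cycles; failed
#' or undetected reactions are stored internally as `NA` (the on-disk sentinel,
#' conventionally 999 in Biomark exports, is normalised on read). Cells flagged
#' `excluded` (doublets, debris) may live in files but never enter a matrix.
#'
#' @param ct numeric matrix, cells in rows and gene assays in columns; `NA`
#'   marks a non-detected reaction.
#' @param meta data frame with columns `cell_id`, `group`, and optionally
#'   `capture_flag` (`"single"` assumed when absent).
#' @param panel character vector of gene assay names; defaults to the column
#'   names of `ct`.
#' @return an object of class `ct_matrix` with elements `ct`, `meta`, `panel`.
#' @export
ct_matrix <- function(ct, meta, panel = colnames(ct)) {
  ct <- as.matrix(ct)
  storage.mode(ct) <- "double"
  fail_if(is.null(panel) || length(panel) == 0L, "gene panel must be non-empty")
  fail_if(anyDuplicated(panel) > 0L, "gene panel names must be unique")
  fail_if(any(!nzchar(panel)), "gene panel names must be non-empty strings")
  fail_if(ncol(ct) != length(panel), "ct columns must match panel size")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  fail_if(!("cell_id" %in% names(meta)), "missing cell_id column")
  fail_if(!("group" %in% names(meta)), "missing group column")
  if (is.null(meta$capture_flag)) meta$capture_flag <- "single"
  dup <- meta$cell_id[duplicated(meta$cell_id)]
  fail_if(length(dup) > 0L, "duplicate cell_id: ", paste(unique(dup), collapse = ", "))
  bad_group <- setdiff(unique(meta$group), GROUP_LEVELS)
  fail_if(length(bad_group) > 0L, "unknown group label: ", paste(bad_group, collapse = ", "))
  bad_flag <- setdiff(unique(meta$capture_flag), c("single", "excluded"))
  fail_if(length(bad_flag) > 0L, "unknown capture_flag: ", paste(bad_flag, collapse = ", "))
  fail_if(nrow(ct) != nrow(meta), "ct rows must match metadata rows")
  bad <- which(!is.na(ct) & (ct <= 0 | ct > 40))
  if (length(bad) > 0L) {
    i <- ((bad[1L] - 1L) %% nrow(ct)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(ct)) + 1L
    stop(sprintf("Ct value out of (0, 40] at cell '%s', gene '%s'",
                 meta$cell_id[i], panel[j]), call. = FALSE)
  }
  # excluded capture sites are dropped from the analysed matrix
  keep <- meta$capture_flag == "single"
  ct <- ct[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  rownames(meta) <- NULL
  dimnames(ct) <- list(meta$cell_id, panel)
  structure(list(ct = ct, meta = meta, panel = panel), class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d cells x %d genes\n", nrow(x$ct), length(x$panel)))
  tab <- table(factor(x$meta$group, levels = GROUP_LEVELS))
  tab <- tab[tab > 0]
  if (length(tab)) cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  non-detect: %.1f%% of reactions\n", 100 * mean(is.na(x$ct))))
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

#' Read a Ct matrix from CSV
#'
#' Two dialects are supported. `wide_csv` has columns `cell_id`, `group`,
#' optionally `capture_flag`, then one numeric column per gene. `long_csv` has
#' columns `cell_id`, `group`, `gene`, `ct` (one row per reaction). In both,
#' the non-detect sentinel (default 999) is normalised to internal censoring.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param dialect `"wide_csv"` or `"long_csv"`.
#' @param nondetect_code sentinel Ct value marking a failed/undetected
#'   reaction (default 999).
#' @return a [ct_matrix()].
#' @export
load_ct_matrix <- function(path, dialect = c("wide_csv", "long_csv"),
                           nondetect_code = 999) {
  dialect <- match.arg(dialect)
  fail_if(!file.exists(path), "file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  fail_if(!("cell_id" %in% names(df)), "missing cell_id column in ", path)
  fail_if(!("group" %in% names(df)), "missing group column in ", path)
  if (dialect == "wide_csv") {
    meta_cols <- intersect(c("cell_id", "group", "capture_flag"), names(df))
    genes <- setdiff(names(df), meta_cols)
    fail_if(length(genes) == 0L, "no gene columns found in ", path)
    ct <- matrix(NA_real_, nrow(df), length(genes))
    for (j in seq_along(genes)) {
      v <- df[[genes[j]]]
      if (!is.numeric(v)) {
        num <- suppressWarnings(as.numeric(v))
        bad <- which(is.na(num) & !is.na(v) & nzchar(trimws(v)))
        fail_if(length(bad) > 0L,
                sprintf("non-numeric Ct at row %d, column '%s': '%s'",
                        bad[1L], genes[j], v[bad[1L]]))
        v <- num
      }
      ct[, j] <- v
    }
    colnames(ct) <- genes
    meta <- df[meta_cols]
  } else {
    need <- c("cell_id", "group", "gene", "ct")
    miss <- setdiff(need, names(df))
    fail_if(length(miss) > 0L, "long_csv missing column(s): ", paste(miss, collapse = ", "))
    if (!is.numeric(df$ct)) {
      num <- suppressWarnings(as.numeric(df$ct))
      bad <- which(is.na(num) & !is.na(df$ct) & nzchar(trimws(df$ct)))
      fail_if(length(bad) > 0L,
              sprintf("non-numeric Ct at row %d, column 'ct': '%s'", bad[1L], df$ct[bad[1L]]))
      df$ct <- num
    }
    cells <- unique(df$cell_id)
    genes <- unique(df$gene)
    ct <- matrix(NA_real_, length(cells), length(genes),
                 dimnames = list(cells, genes))
    ct[cbind(match(df$cell_id, cells), match(df$gene, genes))] <- df$ct
    first <- !duplicated(df$cell_id)
    meta <- data.frame(cell_id = df$cell_id[first], group = df$group[first],
                       stringsAsFactors = FALSE)
    if ("capture_flag" %in% names(df)) meta$capture_flag <- df$capture_flag[first]
  }
  ct[!is.na(ct) & ct == nondetect_code] <- NA_real_
  ct_matrix(ct, meta)
}

#' Write a Ct matrix to CSV
#'
#' Inverse of [load_ct_matrix()]: values are printed with two decimals and
#' censored reactions are written as the sentinel, so write-then-read
#' round-trips the matrix exactly at that precision.
#'
#' @param x a [ct_matrix()].
#' @param path output file path.
#' @inheritParams load_ct_matrix
#' @return `path`, invisibly.
#' @export
write_ct_matrix <- function(x, path, dialect = c("wide_csv", "long_csv"),
                            nondetect_code = 999) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "ct_matrix"))
  ct <- x$ct
  ct[is.na(ct)] <- nondetect_code
  if (dialect == "wide_csv") {
    out <- cbind(x$meta[c("cell_id", "group")],
                 as.data.frame(matrix(sprintf("%.2f", ct), nrow(ct),
                                      dimnames = dimnames(ct)),
                               check.names = FALSE))
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    out <- data.frame(
      cell_id = rep(x$meta$cell_id, times = ncol(ct)),
      group = rep(x$meta$group, times = ncol(ct)),
      gene = rep(x$panel, each = nrow(ct)),
      ct = sprintf("%.2f", as.vector(ct)),
      stringsAsFactors = FALSE)
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
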