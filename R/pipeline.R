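default_config <- function() {
  list(
    seed = 1L,
    outdir = "scqpcr_run",
    lod = 24,
    nondetect_code = 999,
    min_detected = 0L,
    k = 6L,
    linkage = "ward.D2",
    space = "expression",
    m = 20L,
    top_n = 10L,
    include_surgical = FALSE,
    overlap_genes = NULL,
    input = list(ct_path = NULL, bulk_path = NULL, dialect = "wide_csv"),
    simulate = list(enabled = TRUE, n_total = NULL, noise_sd = 0.5,
                    separability = 6, sd_et = 1.5),
    tsne = list(iterations = 2000L, perplexity = 10, theta = 0.5,
                learning_rate = 200, early_exaggeration = 12,
                exaggeration_iter = 250L, momentum = 0.5,
                final_momentum = 0.8, momentum_switch = 250L,
                record_every = 50L),
    stages = list(embed = TRUE, cluster = TRUE, project = TRUE, stats = TRUE)
  )
}

merge_section <- function(defaults, user, path) {
  unknown <- setdiff(names(user), names(defaults))
  fail_if(length(unknown) > 0L, "unknown config key: ",
          paste(paste0(path, unknown), collapse = ", "))
  for (k in names(user)) defaults[[k]] <- user[[k]]
  defaults
}

#' Validate a pipeline configuration
#'
#' Accepts a JSON file path or a named list. Unknown keys are rejected with
#' their key path; missing keys receive documented defaults; every module's
#' parameter constraints are checked before any stage runs.
#'
#' @param config path to a JSON config file, or a named list.
#' @return a validated config list of class `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    fail_if(!file.exists(config), "config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  fail_if(!is.list(config), "config must be a list or a JSON file path")
  def <- default_config()
  nested <- c("input", "simulate", "tsne", "stages")
  flat <- config[setdiff(names(config), nested)]
  out <- merge_section(def[setdiff(names(def), nested)], flat, "")
  for (s in nested)
    out[[s]] <- merge_section(def[[s]], config[[s]] %||% list(), paste0(s, "."))
  fail_if(out$k < 1, "config error: k must be >= 1")
  fail_if(out$lod <= 0 || out$lod > 40, "config error: lod must be in (0, 40]")
  fail_if(out$min_detected < 0, "config error: min_detected must be >= 0")
  fail_if(out$m < 1, "config error: m must be >= 1")
  fail_if(out$top_n < 1, "config error: top_n must be >= 1")
  fail_if(!out$space %in% c("expression", "embedding"),
          "config error: space must be 'expression' or 'embedding'")
  fail_if(out$tsne$perplexity <= 1, "config error: tsne.perplexity must be > 1")
  fail_if(out$tsne$theta < 0 || out$tsne$theta > 1,
          "config error: tsne.theta must be in [0, 1]")
  fail_if(out$tsne$iterations < 1, "config error: tsne.iterations must be >= 1")
  fail_if(!isTRUE(out$simulate$enabled) && is.null(out$input$ct_path),
          "config error: input.ct_path required when simulate is disabled")
  structure(out, class = "run_config")
}

write_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full single-cell qPCR analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate (or load) ->
#' expression transform -> t-SNE embedding -> k-constrained clustering ->
#' bulk projection -> cluster statistics — writing each stage's outputs as
#' CSV/JSON into `outdir` and a `manifest.json` listing every emitted file
#' with its MD5 checksum. A single global seed fans out to per-stage seeds
#' via [stage_seed()], so toggling one stage never perturbs another's
#' stream and identical config + seed reproduces byte-identical outputs.
#' A stage failure aborts with the stage name; prior stages' files are
#' preserved.
#'
#' @param config a config list, JSON path, or [validate_config()] result.
#' @return an object of class `pnx_run` with the in-memory stage results
#'   (`expression`, `embedding`, `assignment`, `frequencies`, `markers`,
#'   `de`, `projection`, `emergent_cluster`), the validated `config`, and
#'   the `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  design <- NULL; programs <- NULL; bulk <- NULL; truth <- NULL; ct_mat <- NULL
  if (isTRUE(config$simulate$enabled)) {
    dp <- default_paper_design(separability = config$simulate$separability,
                               sd_et = config$simulate$sd_et)
    design <- dp$design; programs <- dp$programs
    if (!is.null(config$simulate$n_total))
      design <- scale_design(design, config$simulate$n_total)
    # pre-flight: the perplexity constraint is checkable before any compute
    n_planned <- sum(design$group_sizes)
    fail_if(isTRUE(config$stages$embed) &&
              config$tsne$perplexity >= n_planned / 3,
            "config error: tsne.perplexity must be < n_cells / 3 (n = ",
            n_planned, ")")
    run_stage("simulate", {
      coh <- generate_cohort(design, programs, stage_seed(config$seed, "simulate"),
                             lod = config$lod)
      ct <- coh$ct; truth <- coh$truth
      bk <- generate_bulk(design, programs, noise_sd = config$simulate$noise_sd,
                          seed = stage_seed(config$seed, "bulk"))
      bulk <- bk$bulk
      files <- c(files,
                  write_ct_matrix(ct, file.path(outdir, "cohort.csv"),
                                  nondetect_code = config$nondetect_code),
                  write_bulk_panel(bulk, file.path(outdir, "bulk.csv")),
                  write_ground_truth(truth, file.path(outdir, "truth.json")))
      ct_mat <- ct
    })
  } else {
    run_stage("load", {
      ct_mat <- load_ct_matrix(config$input$ct_path,
                                dialect = config$input$dialect,
                                nondetect_code = config$nondetect_code)
      if (!is.null(config$input$bulk_path))
        bulk <- load_bulk_panel(config$input$bulk_path)
    })
  }

  et <- run_stage("transform", {
    ct_f <- qc_filter(ct_mat, config$min_detected)
    fail_if(nrow(ct_f$ct) == 0L, "no cells pass QC")
    ct_to_expression(ct_f, lod = config$lod)
  })
  n <- nrow(et$et)

  embedding <- NULL
  if (isTRUE(config$stages$embed)) {
    run_stage("embed", {
      fail_if(config$tsne$perplexity >= n / 3,
              "tsne.perplexity must be < n_cells / 3")
      params <- tsne_params(iterations = config$tsne$iterations,
                            perplexity = config$tsne$perplexity,
                            theta = config$tsne$theta,
                            seed = stage_seed(config$seed, "embed"),
                            learning_rate = config$tsne$learning_rate,
                            early_exaggeration = config$tsne$early_exaggeration,
                            exaggeration_iter = config$tsne$exaggeration_iter,
                            momentum = config$tsne$momentum,
                            final_momentum = config$tsne$final_momentum,
                            momentum_switch = config$tsne$momentum_switch,
                            record_every = config$tsne$record_every)
      embedding <- tsne_embed(et, params)
      files <- c(files,
                  write_table(data.frame(cell_id = rownames(embedding$coords),
                                         tsne1 = embedding$coords[, 1],
                                         tsne2 = embedding$coords[, 2]),
                              file.path(outdir, "embedding.csv")),
                  write_table(embedding$kl_trace, file.path(outdir, "trace.csv")))
    })
  }

  assignment <- NULL
  if (isTRUE(config$stages$cluster)) {
    run_stage("cluster", {
      assignment <- cluster_cells(et, k = config$k, space = config$space,
                                   embedding = embedding,
                                   linkage = config$linkage)
      files <- c(files,
                  write_table(data.frame(cell_id = names(assignment$labels),
                                         cluster = unname(assignment$labels)),
                              file.path(outdir, "clusters.csv")),
                  write_table(cbind(data.frame(cluster = seq_len(assignment$k)),
                                    as.data.frame(assignment$centroids)),
                              file.path(outdir, "centroids.csv")))
      if (!is.null(embedding))
        files <- c(files, write_table(overlay_labels(assignment, embedding),
                                       file.path(outdir, "overlay.csv")))
    })
  }

  projection <- NULL
  if (isTRUE(config$stages$project) && !is.null(bulk) &&
      !is.null(embedding) && !is.null(assignment)) {
    run_stage("project", {
      std <- standardize_overlap(et, bulk,
                                 config$overlap_genes %||% bulk$genes)
      sim <- similarity_matrix(std)
      projection <- match_and_project(sim, embedding, assignment,
                                       m = config$m)
      sim_df <- cbind(data.frame(bulk_sample = rownames(sim$values)),
                      as.data.frame(sim$values))
      files <- c(files,
                  write_table(sim_df, file.path(outdir, "similarity.csv")),
                  write_table(projection$matches, file.path(outdir, "projection.csv")))
      jsonlite::write_json(projection$identity,
                           file.path(outdir, "identity.json"),
                           auto_unbox = TRUE, digits = NA)
      files <- c(files, file.path(outdir, "identity.json"))
    })
  }

  frequencies <- NULL; markers <- NULL; de <- NULL; emergent <- NULL
  if (isTRUE(config$stages$stats) && !is.null(assignment)) {
    run_stage("stats", {
      frequencies <- cluster_frequencies(assignment, et$meta)
      emergent <- emergent_cluster(frequencies)
      markers <- rank_markers(et, assignment, top_n = config$top_n)
      de <- prepost_comparison(et, include_surgical = config$include_surgical)
      files <- c(files,
                  write_table(frequencies, file.path(outdir, "frequencies.csv")),
                  write_table(markers, file.path(outdir, "markers.csv")),
                  write_table(de, file.path(outdir, "de.csv")))
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("scqpcr")),
    seed = config$seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass(config),
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  structure(list(config = config, manifest = manifest,
                 expression = et, embedding = embedding,
                 assignment = assignment, projection = projection,
                 frequencies = frequencies, markers = markers, de = de,
                 emergent_cluster = emergent, truth = truth),
            class = "pnx_run")
}

#' @export
print.pnx_run <- function(x, ...) {
  cat("scqpcr pipeline run\n")
  cat(sprintf("  cells: %d, genes: %d, seed: %d\n",
              nrow(x$expression$et), length(x$expression$panel), x$config$seed))
  if (!is.null(x$assignment))
    cat(sprintf("  clusters: %d (sizes %s)\n", x$assignment$k,
                paste(x$assignment$sizes, collapse = ", ")))
  if (!is.null(x$emergent_cluster) && !is.null(x$frequencies)) {
    f <- x$frequencies
    ctrl <- mean(f$fraction[f$cluster == x$emergent_cluster &
                              f$group %in% CONTROL_GROUPS])
    post <- mean(f$fraction[f$cluster == x$emergent_cluster &
                              f$group %in% POST_GROUPS])
    cat(sprintf("  emergent cluster %d: %.2f%% of control cells, %.1f%% post-surgery\n",
                x$emergent_cluster, 100 * ctrl, 100 * post))
  }
  cat(sprintf("  outputs: %d files in %s\n",
              length(x$manifest$files), x$config$outdir))
  invisible(x)
}

#' @export
plot.pnx_run <- function(x, ...) {
  fail_if(is.null(x$embedding), "run has no embedding stage")
  plot(x$embedding, labels = x$assignment$labels, ...)
  invisible(x)
}
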