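#' Default end-to-end run configuration
#'
#' Bundles the synthetic-world, searchlight, latency-grid, enhancement and
#' inference settings for [run_pipeline], with defaults mirroring the
#' standard analysis constants (20 mm patch, 25 ms window, 10 ms step,
#' latencies 0-250 ms in 10 ms increments, delta_h 0.1, alpha 0.01) at
#' desk-scale permutation counts. Every constant is overridable.
#'
#' @param synth A [synth_config].
#' @param searchlight A [searchlight_config].
#' @param latencies_ms Latency grid (ms).
#' @param delta_h TFCE threshold step.
#' @param alpha Corrected significance level.
#' @param n_perm_signflip Sign-flip permutations for map inference.
#' @param n_perm_db Label permutations for clustering indices.
#' @param model_layer Which configured layer provides the target model
#'   stream (default: last layer).
#' @param scheme_for_activations Labelling scheme driving planted clusters.
#' @return A `run_config`.
#' @export
run_config <- function(synth = synth_config(),
                       searchlight = searchlight_config(),
                       latencies_ms = seq(0, 250, 10),
                       delta_h = 0.1,
                       alpha = 0.01,
                       n_perm_signflip = 200L,
                       n_perm_db = 1000L,
                       model_layer = NULL,
                       scheme_for_activations = "phone") {
  if (is.null(model_layer)) {
    model_layer <- utils::tail(names(synth$layer_dims), 1L)
  }
  stopifnot(model_layer %in% names(synth$layer_dims))
  structure(list(synth = synth, searchlight = searchlight,
                 latencies_ms = latencies_ms, delta_h = delta_h,
                 alpha = alpha, n_perm_signflip = as.integer(n_perm_signflip),
                 n_perm_db = as.integer(n_perm_db),
                 model_layer = model_layer,
                 scheme_for_activations = scheme_for_activations),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic pipeline
#'
#' Orchestrates simulate -> model RDM streams -> searchlight latency maps ->
#' TFCE + sign-flip inference -> clustering evaluation, writing each stage's
#' artifacts and an append-only JSON manifest (config echo, seeds, stage
#' timings, file checksums) into `out_dir`. Stages never modify an earlier
#' stage's outputs; a failing stage halts the run with the stage named,
#' retaining partial outputs.
#'
#' @param config A [run_config].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results (`mesh`,
#'   `segments`, `timelines`, `model_stream`, `rho_maps`, `tmap`, `tfce`,
#'   `null`, `pmap`, `report`, `clustering`, `manifest`).
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$synth$seed,
                   started = format(Sys.time(), tz = "UTC"),
                   stages = list())
  files <- character(0)
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(seconds =
                                       round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  sy <- config$synth

  # --- simulate -------------------------------------------------------------
  mesh <- t_stage("simulate_mesh", make_mesh(sy$n_vertices_per_hemisphere,
                                             sy$mesh_radius_mm, sy$seed))
  files <- c(files, write_mesh_tsv(mesh, file.path(out_dir, "mesh")))
  segments <- t_stage("simulate_segments", make_segment_table(sy))
  files <- c(files, write_segments_tsv(segments,
                                       file.path(out_dir, "segments.tsv")))
  schemes <- default_label_schemes()
  timelines <- t_stage("simulate_activations",
                       make_layer_activations(
                         sy, segments,
                         schemes[[config$scheme_for_activations]]))

  # --- model RDM streams ----------------------------------------------------
  model_stream <- t_stage("model_rdms",
                          build_model_stream(timelines[[config$model_layer]]))
  files <- c(files, write_tsv(
    data.frame(layer = config$model_layer,
               time_ms = model_stream$times_ms,
               mean_dissimilarity = vapply(model_stream$rdms, function(r) {
                 mean(vectorize_upper(r))
               }, numeric(1))),
    file.path(out_dir, "model_stream_summary.tsv")))

  # --- source epochs + searchlight latency maps -----------------------------
  epochs <- t_stage("simulate_epochs",
                    make_source_epochs(sy, mesh, model_stream,
                                       epoch_end_ms =
                                         config$searchlight$epoch_ms[2L]))
  rho_maps <- t_stage("latency_maps",
                      searchlight_rho_maps(model_stream, epochs, mesh,
                                           config$searchlight,
                                           config$latencies_ms,
                                           layer = config$model_layer))
  tmap <- t_stage("group_tmap", group_tmap(rho_maps))
  group_mean <- Reduce(`+`, lapply(rho_maps, `[[`, "values")) /
    length(rho_maps)
  peak <- arrayInd(which.max(group_mean), dim(group_mean))
  files <- c(files, write_tsv(
    data.frame(vertex = seq_len(nrow(group_mean)),
               peak_latency_ms =
                 config$latencies_ms[max.col(group_mean)],
               peak_rho = apply(group_mean, 1L, max),
               peak_t = apply(tmap$values, 1L, max)),
    file.path(out_dir, "group_map_summary.tsv")))

  # --- inference ------------------------------------------------------------
  graph <- spatiotemporal_graph(mesh, length(config$latencies_ms))
  tfce <- t_stage("tfce", tfce_transform(tmap, graph, config$delta_h))
  null <- t_stage("signflip_null",
                  signflip_null(rho_maps, graph, config$n_perm_signflip,
                                seed = derive_seed(sy$seed, "signflip"),
                                delta_h = config$delta_h))
  pmap <- corrected_pmap(tfce, null, graph)
  report <- threshold_and_report(pmap, config$alpha, tfce, graph,
                                 config$latencies_ms)
  files <- c(files, write_tsv(report$clusters,
                              file.path(out_dir, "clusters.tsv")))
  files <- c(files, write_tsv(
    data.frame(latency_ms = config$latencies_ms,
               suprathreshold_extent = report$extent_by_latency),
    file.path(out_dir, "extent_by_latency.tsv")))

  # --- clustering evaluation ------------------------------------------------
  clustering <- t_stage("clustering_eval",
                        evaluate_all_schemes(timelines, segments, schemes,
                                             n_perm = config$n_perm_db,
                                             seed = derive_seed(sy$seed,
                                                                "db-perm")))
  files <- c(files, write_tsv(clustering,
                              file.path(out_dir, "clustering_indices.tsv")))

  manifest$peak <- list(vertex = peak[1L],
                        latency_ms = config$latencies_ms[peak[2L]],
                        mean_rho = max(group_mean))
  manifest$effect_vertices <- attr(epochs, "effect_vertices")
  manifest$planted_latency_ms <- attr(epochs, "planted_latency_ms")
  manifest$max_summed_extent <- report$max_summed_extent
  manifest$min_corrected_p <- min(pmap$values)
  manifest$files <- as.list(tools::md5sum(unname(files)))
  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(mesh = mesh, segments = segments, timelines = timelines,
                 model_stream = model_stream, epochs = epochs,
                 rho_maps = rho_maps, tmap = tmap, tfce = tfce, null = null,
                 pmap = pmap, report = report, clustering = clustering,
                 manifest = manifest))
}
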