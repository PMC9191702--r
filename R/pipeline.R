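#' Run the full analysis pipeline from a config
#'
#' Executes the requested stages in order — synthesize or load inputs,
#' extract regions, build the spatial graph, extract and normalize calcium
#' traces, build the functional graph, compute global/local metrics, run
#' null ensembles, and compute community statistics — writing every
#' intermediate as a file in `output_dir`. Each CSV output starts with a
#' comment line carrying a hash of the config, and a `manifest.json`
#' records the config, hash and file list. Identical config and seed give
#' byte-identical CSV outputs.
#'
#' Config fields (JSON file or R list): `seed` and `output_dir` are
#' required. `input` holds either `mask` / `stack` / `frame_interval`
#' (file paths) or `synthetic` (parameters for [make_label_image()] and
#' optionally `calcium` parameters for [make_calcium_stack()]). Optional
#' sections switch stages on: `spatial` (`type` = "type1" | "type2" |
#' "perimeter" with their parameters), `functional` (`percentile`,
#' `n_shuffles`), `null` (`kind`, `n_iterations`), `community` (`p`,
#' `phases`).
#'
#' @param config path to a JSON config file, or an equivalent named list
#' @param quiet suppress progress messages (default FALSE)
#' @return invisibly, a list with the output directory, config hash and
#'   produced objects (regions, graphs, metrics, ...)
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  validate_config(config)
  # hash the analysis parameters only: where the outputs land must not
  # change what they contain
  hash_cfg <- config[setdiff(names(config), "output_dir")]
  hash <- fnv1a_hash(jsonlite::toJSON(hash_cfg, auto_unbox = TRUE))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(...)
    if (!quiet) message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  cat("", file = log_path)  # truncate
  logf("config hash: ", hash)
  seed <- as.integer(config$seed)
  produced <- list(output_dir = out_dir, config_hash = hash)
  files <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(paste0("# config_hash=", hash), con)
    write.csv(df, con, row.names = FALSE)
    close(con)
    files <<- c(files, name)
    logf("wrote ", name)
    path
  }

  # ---- inputs -------------------------------------------------------------
  stack <- NULL
  frame_interval <- config$input$frame_interval %||% NA_real_
  truth <- NULL
  if (!is.null(config$input$synthetic)) {
    sy <- config$input$synthetic
    li <- make_label_image(n_cells = sy$n_cells %||% 20,
                           field_shape = sy$field_shape %||% c(128, 128),
                           radius_range = sy$radius_range %||% c(4, 7),
                           min_gap = sy$min_gap %||% 2,
                           seed = derive_seed(seed, 1))
    mask <- li$mask
    truth <- li$truth
    write_label_mask(mask, file.path(out_dir, "mask.tif"))
    files <- c(files, "mask.tif")
    if (!is.null(sy$calcium)) {
      ca <- sy$calcium
      n_blocks <- ca$n_blocks %||% 2
      labs <- sort(unique(mask[mask > 0]))
      blocks <- split(labs, rep(seq_len(n_blocks), length.out = length(labs)))
      frame_interval <- ca$frame_interval %||% 0.5
      cs <- make_calcium_stack(mask, blocks, snr = ca$snr %||% 5,
                               spike_rate = ca$spike_rate %||% 0.1,
                               T = ca$T %||% 600,
                               frame_interval = frame_interval,
                               seed = derive_seed(seed, 2))
      stack <- cs$stack
      produced$true_adjacency <- cs$true_adjacency
    }
  } else {
    if (is.null(config$input$mask)) stop("config$input needs mask or synthetic")
    if (!file.exists(config$input$mask))
      stop("input mask not found: ", config$input$mask)
    mask <- read_label_mask(config$input$mask,
                            pixel_size = config$input$pixel_size)
    if (!is.null(config$input$stack)) {
      if (!file.exists(config$input$stack))
        stop("input stack not found: ", config$input$stack)
      stack <- read_image_stack(config$input$stack, frame_interval)
    }
  }

  regions <- extract_regions(mask)
  emit(data.frame(label = regions$label, area_px = regions$area,
                  centroid_row = regions$centroid_row,
                  centroid_col = regions$centroid_col,
                  equiv_diameter_px = regions$equiv_diameter,
                  touches_border = regions$touches_border), "regions.csv")
  produced$regions <- regions

  # ---- spatial graph ------------------------------------------------------
  spatial <- NULL
  if (!is.null(config$spatial)) {
    sp <- config$spatial
    spatial <- switch(sp$type,
      type1 = build_type1_graph(mask, expansion = sp$expansion %||% 2),
      type2 = build_type2_graph(regions,
                                scaling_factor = sp$scaling_factor %||% 3),
      perimeter = graph_from_distances(perimeter_distances(regions),
                                       threshold = sp$threshold))
    emit(edge_list(spatial), "spatial_edges.csv")
    emit(global_metrics(spatial, mask), "spatial_global_metrics.csv")
    emit(local_metrics(spatial), "spatial_local_metrics.csv")
    write_graphml(spatial, file.path(out_dir, "spatial_graph.graphml"))
    files <- c(files, "spatial_graph.graphml")
    produced$spatial_graph <- spatial
  }

  # ---- calcium / functional ----------------------------------------------
  if (!is.null(stack) && !is.null(config$functional)) {
    fu <- config$functional
    traces <- extract_traces(stack, mask)
    norm <- normalize_traces(traces)
    emit(data.frame(label = norm$roi_labels,
                    n_spikes = vapply(norm$spikes, length, 1L),
                    active = norm$active), "activity.csv")
    act <- select_active(norm)
    if (nrow(act$dff) >= 2) {
      M <- crosscov_matrix(act)
      thr <- shuffle_null_threshold(act, percentile = fu$percentile %||% 99,
                                    n_shuffles = fu$n_shuffles %||% 1,
                                    seed = derive_seed(seed, 3))
      fg <- build_functional_graph(M, thr)
      logf(sprintf("functional threshold: %.4f", thr))
      emit(edge_list(fg), "functional_edges.csv")
      emit(global_metrics(fg), "functional_global_metrics.csv")
      emit(local_metrics(fg), "functional_local_metrics.csv")
      produced$functional_graph <- fg
      produced$functional_threshold <- thr
    } else {
      logf("fewer than 2 active ROIs; functional graph skipped")
    }
  }

  # ---- null models --------------------------------------------------------
  if (!is.null(config$null)) {
    nu <- config$null
    kind <- nu$kind %||% "degree_preserving"
    src <- if (kind == "degree_preserving") {
      produced$functional_graph %||% spatial
    } else regions
    if (is.null(src)) stop("null stage needs a graph or regions")
    ens <- null_distribution(src, kind = kind,
                             n_iterations = nu$n_iterations %||% 100,
                             seed = derive_seed(seed, 4),
                             field_shape = dim(mask),
                             scaling_factor = config$spatial$scaling_factor %||% 3)
    df <- ens$summary
    df$n_iterations <- ens$n_iterations
    df$kind <- ens$kind
    emit(df, "null_summary.csv")
    produced$null_ensemble <- ens
  }

  # ---- community ----------------------------------------------------------
  if (!is.null(config$community) && !is.null(spatial)) {
    co <- config$community
    phases <- if (!is.null(co$labels_csv)) {
      tb <- read.csv(co$labels_csv)
      setNames(as.character(tb$phase), tb$label)
    } else {
      make_phase_labels(spatial, p = co$p %||% 0.5,
                        phases = co$phases %||% c("G1", "SG2M"),
                        seed = derive_seed(seed, 5))
    }
    ns <- neighborhood_similarity(spatial, phases)
    emit(ns$scores, "neighborhood_scores.csv")
    emit(data.frame(N_S = ns$N_S,
                    n_eligible = sum(!is.na(ns$scores$score))),
         "neighborhood_similarity.csv")
    produced$N_S <- ns$N_S
  }

  manifest <- list(config = config, config_hash = hash, files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("done: ", length(files), " outputs")
  invisible(produced)
}

validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or JSON file path")
  if (is.null(config$seed)) stop("config$seed is required")
  if (is.null(config$output_dir)) stop("config$output_dir is required")
  if (is.null(config$input)) stop("config$input is required")
  if (!is.null(config$spatial)) {
    if (is.null(config$spatial$type) ||
        !config$spatial$type %in% c("type1", "type2", "perimeter"))
      stop("config$spatial$type must be type1, type2 or perimeter")
    if (config$spatial$type == "perimeter" &&
        is.null(config$spatial$threshold))
      stop("perimeter graphs need config$spatial$threshold")
  }
  if (!is.null(config$null) &&
      !(config$null$kind %||% "degree_preserving") %in%
        c("degree_preserving", "random_spatial"))
    stop("config$null$kind must be degree_preserving or random_spatial")
  invisible(TRUE)
}
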