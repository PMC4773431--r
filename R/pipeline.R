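#' Build a pipeline configuration
#'
#' Assembles the per-stage parameter blocks of the full reconstruction
#' pipeline (filter, detect, optional segment, track, score) plus input and
#' seed settings. Defaults reproduce the synthetic benchmark conditions: a
#' generated embryo filtered by 5 iterations of geodesic mean curvature
#' flow, FBLS centre detection, and annealed tracking.
#'
#' @param input list: either `list(type = "synthetic", config =
#'   synthetic_config(...))` or `list(type = "tiff", pattern = ...,
#'   dir = ..., spacing = ..., dt_seconds = ...)`.
#' @param filter list: `enabled`, plus [gmcf_params()] arguments.
#' @param detect list: `method` (`"fbls"` or `"dog"`) and the matching
#'   parameter block.
#' @param segment list: `enabled`; when `TRUE`, a whole-embryo mask and the
#'   cell count/density are computed per frame ([subsurf_params()]
#'   arguments in `params`).
#' @param track list of [anneal_config()] arguments.
#' @param score list: `enabled`, `r_factor`, and optionally `gold` (a path
#'   to a gold-standard lineage CSV; unnecessary for synthetic input, whose
#'   ground truth is used directly).
#' @param seed global seed; stage seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = list(type = "synthetic",
                                         config = synthetic_config()),
                            filter = list(enabled = TRUE, K = 0.01,
                                          sigma_pre = 1, n_iter = 5),
                            detect = list(method = "fbls", delta = 0.2, mu = 1,
                                          n_iter = 10, intensity_floor = 0.2),
                            segment = list(enabled = FALSE),
                            track = list(d_max = 8, n_sweeps = 40,
                                         k_candidates = 6),
                            score = list(enabled = TRUE, r_factor = 0.5),
                            seed = 1L) {
  structure(list(input = input, filter = filter, detect = detect,
                 segment = segment, track = track, score = score,
                 seed = as.integer(seed)), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors the sections of [pipeline_config()]; omitted sections
#' take their defaults. Seeds are never implicit: a missing `seed` key is
#' an error.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("pipeline config must set an explicit seed", call. = FALSE)
  def <- pipeline_config(seed = y$seed)
  for (sec in c("input", "filter", "detect", "segment", "track", "score")) {
    if (!is.null(y[[sec]])) {
      if (identical(sec, "input") && identical(y$input$type, "synthetic")) {
        sc <- do.call(synthetic_config, y$input$config %||% list())
        def$input <- list(type = "synthetic", config = sc)
      } else {
        def[[sec]] <- utils::modifyList(def[[sec]], y[[sec]])
      }
    }
  }
  def
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, frame = NULL, expr) {
  tryCatch(expr, error = function(e) {
    loc <- if (is.null(frame)) name else sprintf("%s (frame %d)", name, frame)
    stop(sprintf("pipeline stage '%s' failed: %s", loc, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full reconstruction pipeline
#'
#' Executes filter, detect, (optional) segment, track and score in
#' sequence, writing all artifacts plus a run manifest (every parameter and
#' seed) to `out_dir`. Re-running with the same configuration reproduces
#' every output byte-identically.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param write_filtered also write the filtered stacks as TIFF (rounded to
#'   16-bit counts).
#' @return Invisibly, a list with the detected centres, the lineage forest,
#'   the score report (if scored), the density table (if segmented), and
#'   the manifest.
#' @export
run_pipeline <- function(config, out_dir, write_filtered = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gold <- NULL
  if (identical(config$input$type, "synthetic")) {
    sc <- config$input$config
    sc$seed <- config$seed
    emb <- .stage("synthetic", NULL, synthetic_embryo(sc))
    dataset <- emb$dataset
    gold <- emb$gold
  } else {
    dataset <- .stage("read", NULL,
                      read_timelapse(config$input$pattern, config$input$dir,
                                     config$input$spacing,
                                     config$input$dt_seconds))
  }
  if (!is.null(config$score$gold))
    gold <- gold_standard(read_lineage(config$score$gold))

  nT <- length(dataset$frames)
  centres <- vector("list", nT)
  fp <- config$filter
  gp <- gmcf_params(K = fp$K %||% 0.01, sigma_pre = fp$sigma_pre %||% 1,
                    n_iter = fp$n_iter %||% 5, tau = fp$tau)
  dtc <- config$detect
  next_id <- 1L
  filtered <- vector("list", nT)
  for (k in seq_len(nT)) {
    g <- dataset$frames[[k]]$nuclei
    if (isTRUE(fp$enabled))
      g <- .stage("filter", k - 1L, gmcf_filter(g, gp))
    filtered[[k]] <- g
    cs <- .stage("detect", k - 1L, {
      if (identical(dtc$method, "dog")) {
        detect_centres(g, "dog",
                       dog_params(dtc$sigma_small %||% 2,
                                  dtc$sigma_large %||% 14,
                                  dtc$threshold_pct %||% 5))
      } else {
        detect_centres(g, "fbls",
                       fbls_params(delta = dtc$delta %||% 0.2,
                                   mu = dtc$mu %||% 1,
                                   n_iter = dtc$n_iter %||% 10,
                                   tau = dtc$tau,
                                   intensity_floor = dtc$intensity_floor %||% 0.2))
      }
    })
    if (nrow(cs)) cs$id <- seq.int(next_id, length.out = nrow(cs))
    next_id <- next_id + nrow(cs)
    centres[[k]] <- cs
  }
  all_centres <- do.call(rbind, centres)
  write_lineage(lineage_forest(all_centres), file.path(out_dir, "centres.csv"))
  if (write_filtered)
    write_timelapse(timelapse_dataset(lapply(filtered, function(g) list(nuclei = g)),
                                      dataset$dt_seconds),
                    out_dir, prefix = "filtered", round_to_int = TRUE)

  density_tab <- NULL
  if (isTRUE(config$segment$enabled)) {
    sp <- do.call(subsurf_params,
                  utils::modifyList(list(g_sigma = 8, seed_width = 20),
                                    config$segment$params %||% list()))
    density_tab <- do.call(rbind, lapply(seq_len(nT), function(k) {
      m <- .stage("segment", k - 1L,
                  suppressWarnings(segment_embryo(filtered[[k]], sp)))
      cd <- cell_density(centres[[k]], m)
      data.frame(t = k - 1L, count = cd$count, density = cd$density,
                 volume_um3 = m$volume_um3)
    }))
    utils::write.csv(density_tab, file.path(out_dir, "density.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  tcfg <- do.call(anneal_config,
                  utils::modifyList(list(seed = config$seed + 1L), config$track))
  forest <- .stage("track", NULL, track_centres(all_centres, tcfg))
  write_lineage(forest, file.path(out_dir, "lineage.csv"))

  report <- NULL
  if (isTRUE(config$score$enabled) && !is.null(gold)) {
    report <- .stage("score", NULL,
                     score_lineages(forest, gold,
                                    r_factor = config$score$r_factor %||% 0.5))
    jsonlite::write_json(.report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (identical(config$input$type, "synthetic"))
      write_lineage(gold$forest, file.path(out_dir, "gold.csv"))
  }

  manifest <- list(package_version = as.character(utils::packageVersion("embryotrack")),
                   seed = config$seed,
                   stage_seeds = list(synthetic = config$seed,
                                      track = config$seed + 1L),
                   config = .config_to_list(config),
                   outputs = list.files(out_dir))
  manifest$outputs <- setdiff(manifest$outputs, "manifest.json")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(centres = all_centres, forest = forest, report = report,
                 density = density_tab, manifest = manifest, gold = gold))
}

.config_to_list <- function(config) {
  out <- unclass(config)
  if (identical(out$input$type, "synthetic"))
    out$input$config <- unclass(out$input$config)
  out
}

.report_to_list <- function(report) {
  cat_list <- function(name) {
    m <- report$metrics[[name]]
    cc <- m$counts
    list(TP = cc$TP, FP = cc$FP, FN = cc$FN,
         WL = if (is.na(cc$WL)) NULL else cc$WL,
         ML = if (is.na(cc$ML)) NULL else cc$ML,
         sensitivity = m$sensitivity,
         false_detection_rate = m$false_detection_rate,
         fn_rate = m$fn_rate)
  }
  out <- list(centres = cat_list("centres"), links = cat_list("links"),
              mitoses = cat_list("mitoses"),
              lineage_score = report$lineage_score)
  if (!is.null(report$windows))
    out$windows <- lapply(report$windows, function(w)
      list(t_start = w$window[1], t_end = w$window[2],
           centres = list(sensitivity = w$metrics$centres$sensitivity),
           links = list(sensitivity = w$metrics$links$sensitivity),
           mitoses = list(sensitivity = w$metrics$mitoses$sensitivity)))
  out
}
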