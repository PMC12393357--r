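#' Run the full analysis pipeline
#'
#' Chains the analysis path end to end: (simulate or load a stack) ->
#' register -> detect cells (or load ROIs) -> convert to DF/F -> extract
#' traces -> smooth -> detect peaks -> classify epoch responses -> export the
#' signal/peaks CSV pair. Every product is written under `out_dir` together
#' with a resolved copy of the configuration, and stages are individually
#' skippable. Given a fixed configuration (and seed, when simulating) the
#' outputs are byte-identical across runs.
#'
#' @param config a nested list or the path of a YAML file. Recognized blocks
#'   (all optional unless noted):
#'   \describe{
#'     \item{input}{`path:` a TIFF stack, or `preset:`/`spec:` for the
#'       synthetic generator (uses `seed`). Required.}
#'     \item{seed}{integer seed for the synthetic generator.}
#'     \item{register}{`enabled:` (default `TRUE`), `reference_frame`,
#'       `max_shift`, `template_rect` (x, y, w, h).}
#'     \item{rois}{`path:` an ImageJ `.roi`/`.zip`; bypasses segmentation.}
#'     \item{segment}{[segmentation_params()] fields.}
#'     \item{dff}{`baseline_start`, `baseline_end` (required), `epsilon`.}
#'     \item{smooth}{`sigma` (default 1; 0 disables).}
#'     \item{detect}{[peak_params()] fields.}
#'     \item{classify}{`epochs:` list of `label`/`start`/`end`,
#'       `criteria:` [response_criteria()] fields, `response_window`,
#'       `off_label`, `on_label` (epoch labels designated as the
#'       light-extinction and light-return epochs).}
#'     \item{export}{`prefix` (default `"sample"`).}
#'   }
#' @param out_dir output directory (created if needed); defaults to
#'   `config$out_dir` or a temporary directory.
#' @return (invisibly) the manifest: a named list of product paths plus the
#'   in-memory results (`traces`, `peaks`, `labels`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir %||% tempfile("calmov_run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(out_dir = out_dir)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  # --- input ---------------------------------------------------------------
  input <- stage("input", {
    inp <- config$input
    if (is.null(inp)) stop("config has no input block")
    if (!is.null(inp$path)) {
      list(stack = read_stack(inp$path), truth = NULL)
    } else if (!is.null(inp$preset)) {
      extra <- inp[setdiff(names(inp), "preset")]
      spec <- do.call(scene_preset, c(list(name = inp$preset,
                                           seed = config$seed %||% 1), extra))
      sim <- render_movie(spec)
      list(stack = sim$stack, truth = sim$truth, epochs = spec$epochs)
    } else stop("input needs 'path' or 'preset'")
  })
  stack <- input$stack
  manifest$truth <- input$truth

  # --- registration --------------------------------------------------------
  reg_cfg <- config$register %||% list()
  if (!isFALSE(reg_cfg$enabled)) {
    res <- stage("register", {
      p <- registration_params(
        reference_frame = reg_cfg$reference_frame %||% 1,
        template_rect = if (!is.null(reg_cfg$template_rect))
          unlist(reg_cfg$template_rect),
        max_shift = reg_cfg$max_shift %||% 20)
      register(stack, p)
    })
    stack <- res$stack
    manifest$shifts <- file.path(out_dir, "shifts.csv")
    write_shifts(res$shifts, manifest$shifts)
    manifest$registered <- file.path(out_dir, "registered.tif")
    write_stack(stack, manifest$registered)
  }

  # --- cell detection / ROI loading ---------------------------------------
  rois <- stage("segment", {
    if (!is.null(config$rois$path)) {
      read_imagej_rois(config$rois$path)
    } else {
      seg_cfg <- config$segment %||% list()
      p <- segmentation_params(
        projection = seg_cfg$projection %||% "sum",
        rolling_ball_radius = seg_cfg$rolling_ball_radius %||% 20,
        threshold = seg_cfg$threshold %||% "otsu",
        min_area = seg_cfg$min_area %||% 20,
        max_area = seg_cfg$max_area %||% 400,
        watershed = seg_cfg$watershed %||% TRUE)
      segment_stack_to_rois(stack, p)
    }
  })
  if (length(rois) == 0) stop("stage 'segment': no ROIs detected")
  manifest$rois <- file.path(out_dir,
                             if (length(rois) == 1) "rois.roi" else "rois.zip")
  write_imagej_rois(rois, manifest$rois)
  manager <- cell_manager(rois)

  # --- DF/F ----------------------------------------------------------------
  dff <- stage("dff", {
    d <- config$dff
    if (is.null(d)) stop("config has no dff block")
    convert_stack_to_dff(stack, dff_params(d$baseline_start, d$baseline_end,
                                           epsilon = d$epsilon))
  })
  manifest$dff <- file.path(out_dir, "dff.tif")
  write_stack(dff, manifest$dff)

  # --- traces --------------------------------------------------------------
  traces <- stage("extract", extract_traces(dff, rois))
  sigma <- (config$smooth %||% list())$sigma %||% 1
  if (sigma > 0) traces <- stage("smooth", gaussian_smooth(traces, sigma))

  # --- peaks ---------------------------------------------------------------
  det_cfg <- config$detect %||% list()
  peaks <- stage("detect", detect_peaks_traces(traces, peak_params(
    lag = det_cfg$lag %||% 30,
    threshold = det_cfg$threshold %||% 3,
    influence = det_cfg$influence %||% 0.5)))

  # --- classification ------------------------------------------------------
  labels <- NULL
  cls_cfg <- config$classify
  if (!is.null(cls_cfg)) {
    labels <- stage("classify", {
      # YAML 1.1 reads bare ON/OFF as booleans; map them back to labels
      delabel <- function(x) {
        if (isTRUE(x)) "ON" else if (isFALSE(x)) "OFF" else as.character(x)
      }
      ep <- if (!is.null(cls_cfg$epochs)) {
        epoch_set(vapply(cls_cfg$epochs, function(e) delabel(e$label), ""),
                  vapply(cls_cfg$epochs, function(e) as.numeric(e$start), 0),
                  vapply(cls_cfg$epochs, function(e) as.numeric(e$end), 0))
      } else if (!is.null(input$epochs)) {
        input$epochs  # simulated input: classify against its own protocol
      } else stop("classify block needs 'epochs'")
      cr_cfg <- cls_cfg$criteria %||% list()
      crit <- response_criteria(mode = cr_cfg$mode %||% "consecutive",
                                k = cr_cfg$k %||% 3, m = cr_cfg$m,
                                direction = cr_cfg$direction %||% "increase")
      off_lab <- delabel(cls_cfg$off_label %||% "OFF")
      on_lab <- delabel(cls_cfg$on_label %||% "ON2")
      if (!off_lab %in% ep$label || !on_lab %in% ep$label)
        stop("designated OFF/ON epoch labels not found in epochs")
      rw <- cls_cfg$response_window
      types <- character(nrow(peaks$flags))
      for (i in seq_len(nrow(peaks$flags))) {
        resp <- classify_epoch_response(peaks$flags[i, ], ep, crit,
                                        response_window = rw)
        types[i] <- label_response_type(resp[[off_lab]], resp[[on_lab]])
      }
      data.frame(ROI = peaks$roi_names, class = types,
                 stringsAsFactors = FALSE)
    })
    manifest$labels <- file.path(out_dir, "labels.csv")
    con <- file(manifest$labels, "wb")
    writeLines(c("ROI,class",
                 paste(csv_quote(labels$ROI), labels$class, sep = ",")),
               con, sep = "\n")
    close(con)
  }

  # --- export --------------------------------------------------------------
  prefix <- (config$export %||% list())$prefix %||% "sample"
  paths <- stage("export", export_data(manager, traces, peaks,
                                       file.path(out_dir, prefix)))
  manifest$signal <- unname(paths["signal"])
  manifest$peaks_csv <- unname(paths["peaks"])

  # resolved config for provenance
  manifest$config <- file.path(out_dir, "config_resolved.yaml")
  cfg_out <- config
  cfg_out$out_dir <- out_dir
  yaml::write_yaml(cfg_out, manifest$config)

  manifest$traces <- traces
  manifest$peaks <- peaks
  manifest$label_table <- labels
  invisible(manifest)
}
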