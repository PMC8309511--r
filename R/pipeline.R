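#' Default pipeline configuration
#'
#' Materializes every tunable of the simulate/detect/windows/train/classify/
#' visualize/evaluate pipeline. Values can be overridden by a YAML config
#' file and by command-line flags, in that order of precedence.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    rate_hz = 40,
    pattern = "four_target",
    transitions_s = c(0.2, 0.2, 0.2),
    stops = TRUE,
    detector = list(algo = "ivt", params = list()),
    window = list(extent_deg = 32, resolution_px = 64, history_n = 8),
    train = list(arch = "alexnet_like", epochs = 5, n_per_class = 500,
                 split = 0.8),
    classify = list(min_run = 2),
    canvas = list(width_px = 480, height_px = 360,
                  xlim = c(-20, 20), ylim = c(-15, 15)),
    geometry = list(width_px = 1920, height_px = 1080,
                    physical_width_mm = 510, physical_height_mm = 287,
                    viewing_distance_mm = 600)
  )
}

.config_geometry <- function(config) {
  g <- config$geometry
  screen_geometry(g$width_px, g$height_px, g$physical_width_mm,
                  g$physical_height_mm, g$viewing_distance_mm)
}

.config_canvas <- function(config) {
  cv <- config$canvas
  gaze_canvas(cv$width_px, cv$height_px, cv$xlim, cv$ylim)
}

.config_window_spec <- function(config) {
  w <- config$window
  window_spec(w$extent_deg, w$resolution_px, w$history_n)
}

#' Run the gaze-analysis pipeline
#'
#' Executes the requested stages in order, writing each stage's outputs
#' under `out_dir` together with a `manifest.csv` (stage, file) and an echo
#' of the fully materialized configuration (`config.yaml`) for provenance.
#' Stages depend on earlier outputs: `detect`, `windows`, `classify` and
#' `visualize` need `simulate`'s gaze/truth files (or a `gaze_csv` entry in
#' the config pointing at an existing recording in degrees), `train` needs a
#' dataset, and `evaluate` needs detected events plus truth. A missing
#' upstream artifact raises an error naming the stage to run first.
#'
#' @param config Configuration list (see [default_config()]); partial lists
#'   are completed with defaults.
#' @param stages Character subset of `simulate`, `detect`, `windows`,
#'   `train`, `classify`, `visualize`, `evaluate`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly; outputs listed in its manifest.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "detect", "visualize",
                                    "evaluate"),
                         out_dir = tempfile("gazerun")) {
  config <- utils::modifyList(default_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(stage = character(0), file = character(0))
  note <- function(stage, file) {
    manifest <<- rbind(manifest, data.frame(stage = stage, file = file))
  }
  geom <- .config_geometry(config)
  path <- function(f) file.path(out_dir, f)

  sim <- NULL
  load_sim <- function() {
    if (!is.null(sim)) return(sim)
    if (file.exists(path("gaze.csv")) && file.exists(path("truth.csv"))) {
      rec <- read_gaze_csv(path("gaze.csv"), geom, "degrees",
                           config$rate_hz)
      truth <- utils::read.csv(path("truth.csv"),
                               stringsAsFactors = FALSE)$label
      sc <- .config_script(config)
      sim <<- list(recording = rec, truth = truth,
                   stimulus = script_to_stimulus_signal(sc, config$rate_hz))
      return(sim)
    }
    if (!is.null(config$gaze_csv)) {
      rec <- read_gaze_csv(config$gaze_csv, geom, "degrees",
                           config$rate_hz)
      sim <<- list(recording = rec, truth = NULL, stimulus = NULL)
      return(sim)
    }
    stop("no recording available; run the 'simulate' stage first")
  }

  for (stage in stages) {
    if (stage == "simulate") {
      sc <- .config_script(config)
      sim <- simulate_gaze(sc, config$rate_hz,
                           oculomotor_params(seed = config$seed), geom)
      write_gaze_csv(sim$recording, path("gaze.csv"))
      utils::write.csv(
        data.frame(index = seq_along(sim$truth), label = sim$truth),
        path("truth.csv"), row.names = FALSE, quote = FALSE)
      note("simulate", "gaze.csv"); note("simulate", "truth.csv")
    } else if (stage == "detect") {
      s <- load_sim()
      ev <- detect_events(s$recording, config$detector$algo,
                          config$detector$params)
      write_events_csv(ev, path("events.csv"))
      note("detect", "events.csv")
    } else if (stage == "windows") {
      s <- load_sim()
      if (is.null(s$truth)) stop("'windows' needs truth; run 'simulate' first")
      spec <- .config_window_spec(config)
      n_avail <- table(behavior_labels(s$truth))
      n_pc <- min(config$train$n_per_class,
                  n_avail[["stare"]], n_avail[["move"]])
      build_dataset(list(s), spec, n_per_class = n_pc,
                    split = config$train$split, seed = config$seed,
                    out_dir = path("dataset"))
      note("windows", "dataset")
    } else if (stage == "train") {
      spec <- .config_window_spec(config)
      ds <- synthetic_behavior_dataset(
        n_per_class = config$train$n_per_class,
        split = config$train$split, seed = config$seed,
        rate_hz = config$rate_hz, spec = spec)
      model <- train_behavior_classifier(config$train$arch, ds,
                                         epochs = config$train$epochs,
                                         seed = config$seed)
      save_checkpoint(model, path("model.ckpt"))
      utils::write.csv(model$history, path("train_report.csv"),
                       row.names = FALSE, quote = FALSE)
      note("train", "model.ckpt"); note("train", "train_report.csv")
    } else if (stage == "classify") {
      s <- load_sim()
      if (!file.exists(path("model.ckpt"))) {
        stop("'classify' needs a model; run 'train' first")
      }
      model <- load_checkpoint(path("model.ckpt"))
      spec <- .config_window_spec(config)
      seg <- classify_recording(model, s$recording, spec,
                                config$classify$min_run)
      write_events_csv(seg, path("segments.csv"))
      note("classify", "segments.csv")
    } else if (stage == "visualize") {
      s <- load_sim()
      if (!file.exists(path("events.csv"))) {
        stop("'visualize' needs events; run 'detect' first")
      }
      ev <- read_events_csv(path("events.csv"))
      cv <- .config_canvas(config)
      write_raster_png(render_heatmap(ev, s$recording, cv),
                       path("heatmap.png"))
      write_raster_png(render_scanpath(ev, s$recording, cv),
                       path("scanpath.png"))
      write_raster_png(render_abstract_movement(ev, s$recording, cv),
                       path("abstract.png"))
      for (f in c("heatmap.png", "scanpath.png", "abstract.png")) {
        note("visualize", f)
      }
    } else if (stage == "evaluate") {
      s <- load_sim()
      if (!file.exists(path("events.csv"))) {
        stop("'evaluate' needs events; run 'detect' first")
      }
      ev <- read_events_csv(path("events.csv"))
      pred <- labels_from_segments(ev, nrow(s$recording$samples))
      scores <- list(
        fqns = fqns(ev, s$stimulus),
        fqls = fqls(ev, s$stimulus)
      )
      if (!is.null(s$truth)) {
        f1 <- event_f1(pred, s$truth)
        scores$f1 <- stats::setNames(as.list(f1$f1), f1$class)
      }
      jsonlite::write_json(scores, path("scores.json"), auto_unbox = TRUE,
                           digits = NA)
      note("evaluate", "scores.json")
    } else {
      stop("unknown stage: ", stage)
    }
  }
  yaml::write_yaml(config, path("config.yaml"))
  utils::write.csv(manifest, path("manifest.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(out_dir)
}

.config_script <- function(config) {
  if (config$pattern == "four_target") {
    make_script("four_target", transitions_s = config$transitions_s)
  } else if (config$pattern == "custom") {
    make_script("custom", waypoints = as.data.frame(config$waypoints))
  } else {
    make_script(config$pattern, stops = isTRUE(config$stops))
  }
}
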