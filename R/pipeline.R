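# Reproducible multi-stage runs: configuration, execution, provenance.

#' Build a run configuration
#'
#' A plain serializable list of stage parameters. Every [run_pipeline()]
#' call writes the resolved configuration beside its outputs so a run can
#' be reproduced bit-identically.
#'
#' @param seed integer RNG seed for the synthetic stage.
#' @param stages character vector drawn from
#'   `c("simulate", "register", "stmap", "frequency")`, executed in that
#'   order.
#' @param scene,motility named lists of overrides for [scene_config()] /
#'   [motility_config()].
#' @param motion a data frame pose schedule (see [motion_config()]) or
#'   `NULL`.
#' @param normal_length ST-map profile length, px.
#' @param band frequency band `(f_lo, f_hi)` Hz.
#' @param rows map rows for the cross-section series; `NULL` picks rows
#'   around the first ground-truth contraction site.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       stages = c("simulate", "register", "stmap",
                                  "frequency"),
                       scene = list(), motility = list(), motion = NULL,
                       normal_length = 40, band = c(0.1, 2.0),
                       rows = NULL) {
  stopifnot(all(stages %in% c("simulate", "register", "stmap", "frequency")))
  structure(list(seed = as.integer(seed), stages = stages, scene = scene,
                 motility = motility, motion = motion,
                 normal_length = normal_length, band = band, rows = rows),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `path` invisibly / the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$motion)) x$motion <- as.data.frame(x$motion)
  cfg <- run_config(seed = x$seed, stages = x$stages,
                    scene = as.list(x$scene), motility = as.list(x$motility),
                    motion = x$motion, normal_length = x$normal_length,
                    band = x$band, rows = x$rows)
  cfg
}

#' Run the synthetic-to-frequency pipeline into an artifact directory
#'
#' Executes the requested stages in order, writing each stage's outputs
#' (TIFF stacks, CSV tables, JSON reports), a resolved `config.json`, and a
#' plain-text log with stage timings. Deterministic given the seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results (`scene`,
#'   `registered`, `st_map`, `frequency`) and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  cat("", file = logf)
  logmsg <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)), file = logf, append = TRUE)
  }
  write_run_config(config, file.path(out_dir, "config.json"))
  res <- list(out_dir = out_dir)

  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fn(), error = function(e) {
      file.create(file.path(out_dir, "FAILED"))
      logmsg("stage %s FAILED: %s", name, conditionMessage(e))
      stop("stage ", name, " failed: ", conditionMessage(e))
    })
    logmsg("stage %s done in %.2f s", name, proc.time()[["elapsed"]] - t0)
    out
  }

  if ("simulate" %in% config$stages) {
    res$scene <- run_stage("simulate", function() {
      sc <- do.call(scene_config, c(config$scene,
                                    list(rng_seed = config$seed)))
      mo <- do.call(motility_config, config$motility)
      mt <- if (is.null(config$motion)) NULL else
        motion_config(as.data.frame(config$motion))
      sim <- render_motility_video(sc, mo, mt)
      write_video(sim$video, file.path(out_dir, "scene.tif"))
      write_centerline(sim$truth$centerline_px,
                       file.path(out_dir, "centerline.csv"))
      jsonlite::write_json(
        list(contraction_frequency = sim$truth$contraction_frequency,
             pattern = sim$truth$pattern,
             sites_mm = sim$truth$sites_mm,
             diameter_range = sim$truth$diameter_range),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
        null = "null")
      sim
    })
  }
  if ("register" %in% config$stages) {
    res$registered <- run_stage("register", function() {
      video <- res$scene$video %||%
        read_video(file.path(out_dir, "scene.tif"))
      reg <- register_video(video)
      write_video(reg$video, file.path(out_dir, "registered.tif"))
      utils::write.csv(reg$poses, file.path(out_dir, "transforms.csv"),
                       row.names = FALSE)
      reg
    })
  }
  if ("stmap" %in% config$stages) {
    res$st_map <- run_stage("stmap", function() {
      cl_path <- file.path(out_dir, "centerline.csv")
      if (is.null(res$scene) && !file.exists(cl_path)) {
        stop("no centerline available: run the simulate stage or provide ",
             cl_path)
      }
      curve_px <- res$scene$truth$centerline_px %||% read_centerline(cl_path)
      if (!is.null(res$registered)) {
        video <- res$registered$video
        tr1 <- res$registered$transforms[[1]]
        pose1 <- res$scene$truth$pose[1, ]
        ctr <- c((dim(video)[2] + 1) / 2, (dim(video)[1] + 1) / 2)
        posed <- apply_pose(curve_px, pose1$angle,
                            c(pose1$cx, pose1$cy), ctr)
        curve_px <- apply_transform(tr1, posed)
      } else {
        video <- res$scene$video
      }
      S <- st_map_from_video(video, curve_px, config$normal_length)
      utils::write.csv(unclass(S), file.path(out_dir, "stmap.csv"),
                       row.names = FALSE)
      S
    })
  }
  if ("frequency" %in% config$stages) {
    res$frequency <- run_stage("frequency", function() {
      S <- res$st_map
      if (is.null(S)) stop("frequency stage requires the stmap stage")
      rows <- config$rows
      if (is.null(rows)) {
        pp <- attr(S, "pixel_pitch")
        site <- res$scene$truth$sites_mm[1] %||%
          (nrow(S) / 2 * (pp %||% 1))
        ctr_row <- round(site / (pp %||% 1))
        rows <- max(1, ctr_row - 3):min(nrow(S), ctr_row + 3)
      }
      fr <- peak_frequency(cross_section_series(S, rows),
                           band = config$band)
      jsonlite::write_json(
        list(peak_frequency_hz = fr$peak_frequency,
             bin_width_hz = fr$bin_width, band_hz = fr$band, rows = rows),
        file.path(out_dir, "frequency.json"), auto_unbox = TRUE,
        digits = NA)
      fr
    })
  }
  invisible(res)
}
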