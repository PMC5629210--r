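# Plain-text IO: CSV tables for recoil/FRAP/track data, TIFF for images,
# JSON for network model configs.

#' Write / read recoil series tables
#'
#' CSV layout: `experiment, condition, junction_id, frame, time_s,
#' distance_um, phase` with the pre-ablation frame flagged `phase = "pre"`
#' (its distance is L0) and post-ablation frames `"post"`.
#'
#' @param series_list list of `recoil_series`.
#' @param path CSV path.
#' @return `read_recoil_csv` returns a list of `recoil_series`.
#' @export
write_recoil_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    rbind(data.frame(experiment = attr(s, "experiment"),
                     condition = attr(s, "condition"),
                     junction_id = attr(s, "junction_id"),
                     frame = 1L, time_s = 0, distance_um = attr(s, "L0"),
                     phase = "pre", stringsAsFactors = FALSE),
          data.frame(experiment = attr(s, "experiment"),
                     condition = attr(s, "condition"),
                     junction_id = attr(s, "junction_id"),
                     frame = seq_len(nrow(s)) + 1L, time_s = s$time_s,
                     distance_um = s$distance_um, phase = "post",
                     stringsAsFactors = FALSE))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recoil_csv
#' @export
read_recoil_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  keys <- unique(df[c("experiment", "condition", "junction_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    d <- df[df$experiment == keys$experiment[i] &
              df$condition == keys$condition[i] &
              df$junction_id == keys$junction_id[i], ]
    pre <- d[d$phase == "pre", ]
    post <- d[d$phase == "post", ]
    recoil_series(post$time_s, post$distance_um, L0 = pre$distance_um[1],
                  condition = keys$condition[i],
                  experiment = keys$experiment[i],
                  junction_id = keys$junction_id[i])
  })
}

#' Write / read FRAP series tables
#'
#' CSV layout: `experiment, condition, junction_id, frame, time_s,
#' intensity, phase` with phases `pre` (pre-bleach frames), `bleach` (the
#' first post-bleach frame, F(0)) and `post`.
#'
#' @param series_list list of `frap_series`.
#' @param path CSV path.
#' @return `read_frap_csv` returns a list of `frap_series`.
#' @export
write_frap_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    n_pre <- attr(s, "n_prebleach")
    phase <- c(rep("pre", n_pre), "bleach", rep("post", nrow(s) - n_pre - 1))
    data.frame(experiment = attr(s, "experiment"),
               condition = attr(s, "condition"),
               junction_id = attr(s, "junction_id"),
               frame = seq_len(nrow(s)), time_s = s$time_s,
               intensity = s$intensity, phase = phase,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_csv
#' @export
read_frap_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  keys <- unique(df[c("experiment", "condition", "junction_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    d <- df[df$experiment == keys$experiment[i] &
              df$condition == keys$condition[i] &
              df$junction_id == keys$junction_id[i], ]
    d <- d[order(d$frame), ]
    frap_series(d$time_s, d$intensity, n_prebleach = sum(d$phase == "pre"),
                junction_id = keys$junction_id[i],
                condition = keys$condition[i],
                experiment = keys$experiment[i])
  })
}

#' Write / read track tables
#'
#' CSV layout: `track_id, frame, time_min, x_um, y_um, condition,
#' experiment`.
#' @param tracks a `track_set`.
#' @param path CSV path.
#' @export
write_tracks_csv <- function(tracks, path) {
  df <- as.data.frame(tracks)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  track_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read calibrated images as TIFF
#'
#' Intensities are stored as 16-bit samples scaled by 1/65535, so integer
#' intensities up to 65535 a.u. round-trip exactly. Pixel size travels in
#' the sidecar arguments (TIFF tags are not relied upon).
#'
#' @param image a `calibrated_image` (2D or 3D).
#' @param path TIFF path.
#' @param pixel_size_um,z_spacing_um,apical_end calibration for reading.
#' @export
write_tiff_image <- function(image, path) {
  arr <- unclass(image) / 65535
  assert_that(max(arr) <= 1, "intensities above 65535 a.u. not supported")
  if (length(dim(arr)) == 3) {
    planes <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
    tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(arr, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' @rdname write_tiff_image
#' @export
read_tiff_image <- function(path, pixel_size_um, z_spacing_um = NULL,
                            apical_end = "last") {
  planes <- tiff::readTIFF(path, all = TRUE)
  arr <- if (length(planes) == 1) planes[[1]] * 65535
  else array(unlist(planes), dim = c(dim(planes[[1]]), length(planes))) * 65535
  calibrated_image(arr, pixel_size_um, z_spacing_um, apical_end)
}

#' Write / read a network model config (JSON)
#'
#' Serializes nodes, signed edges with per-edge parameters, per-node basal
#' and removal rates, the exogenous species and the forcing schedule.
#'
#' @param model an `srgap_network`.
#' @param path JSON path.
#' @export
write_network_config <- function(model, path) {
  cfg <- list(nodes = model$nodes, edges = model$edges,
              basal = as.list(model$basal),
              removal = as.list(model$removal),
              exogenous = model$exogenous, forcing = model$forcing)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  srgap_network(cfg$nodes, cfg$edges, unlist(cfg$basal),
                unlist(cfg$removal), exogenous = cfg$exogenous,
                forcing = cfg$forcing)
}

#' Write a trajectory as tidy CSV (time, node, value)
#' @param traj a `network_trajectory`.
#' @param path CSV path.
#' @export
write_trajectory_csv <- function(traj, path) {
  nodes <- setdiff(names(traj), "time")
  tidy <- do.call(rbind, lapply(nodes, function(nd)
    data.frame(time = traj$time, node = nd, value = traj[[nd]],
               stringsAsFactors = FALSE)))
  utils::write.csv(tidy, path, row.names = FALSE)
  invisible(path)
}
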