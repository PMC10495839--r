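# File formats. All CSV/JSON outputs use 0-based frame and pixel indices
# (documented in headers/field names); the R API is 1-based.

natural_order <- function(files) {
  num <- suppressWarnings(as.numeric(gsub("\\D", "", basename(files))))
  if (anyNA(num)) order(basename(files)) else order(num, basename(files))
}

#' Read an image time series from TIFF
#'
#' Accepts a multi-page TIFF or a directory of numbered single-page TIFFs
#' (ordered by the number embedded in the filename).
#'
#' @param path File or directory path.
#' @param frame_period Frame period, seconds (metadata is not parsed from
#'   the TIFF).
#' @param pixel_size Pixel size, um/pixel.
#' @return An [image_time_series()].
#' @export
read_stack <- function(path, frame_period = 1 / 0.57,
                       pixel_size = 713 / 512) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                        ignore.case = TRUE)
    if (length(files) == 0L) stop("no TIFF files in ", path, call. = FALSE)
    files <- files[natural_order(files)]
    pages <- lapply(files, function(f) {
      p <- tiff::readTIFF(f, all = TRUE)
      if (is.list(p)) p else list(p)
    })
    pages <- do.call(c, pages)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # first channel of color pages
    p
  })
  if (length(pages) < 2L) {
    stop("an image time series needs at least 2 frames", call. = FALSE)
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("frames have mixed shapes", call. = FALSE)
  }
  frames <- array(unlist(pages, use.names = FALSE),
                  dim = c(dims[1, 1], dims[2, 1], length(pages)))
  image_time_series(frames, frame_period, pixel_size)
}

#' Write an image time series as a 16-bit multi-page TIFF
#'
#' Intensities are clipped to `[0, 1]` and stored as 16-bit grayscale
#' (one page per frame). Values already on the 16-bit grid (as produced by
#' [simulate_angiogram()]) round trip bit-identically.
#'
#' @param stack An [image_time_series()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_time_series"))
  pages <- lapply(seq_len(n_frames(stack)), function(t) {
    pmin(pmax(stack$frames[, , t], 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

# strip S3 classes (including the nested frame-level table) for JSON
confusion_plain <- function(cmp) {
  out <- unclass(cmp)
  if (!is.null(out$frame_level)) out$frame_level <- unclass(out$frame_level)
  out
}

stallogram_to_df <- function(sg) {
  df <- as.data.frame(sg$matrix * 1L)
  colnames(df) <- paste0("frame_", seq_len(ncol(sg$matrix)) - 1L)
  cbind(data.frame(capillary_id = sg$capillary_ids), df)
}

#' Write analysis results to a directory
#'
#' Writes `stallogram.csv` (rows = capillaries, columns = 0-based frame
#' indices, values 0/1), `events.csv` (0-based inclusive frames),
#' `statistics.json` and, when supplied, `confusion.json`. Column
#' ordering is deterministic and numeric fields keep full precision.
#'
#' @param sg A [stallogram()].
#' @param events Stall-event data frame.
#' @param statistics A [compute_statistics()] result (optional).
#' @param confusion A [confusion_rates()] result (optional).
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_results <- function(sg, events, statistics = NULL, confusion = NULL,
                          out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(stallogram = file.path(out_dir, "stallogram.csv"),
             events = file.path(out_dir, "events.csv"))
  write.csv(stallogram_to_df(sg), paths["stallogram"], row.names = FALSE,
            quote = FALSE)
  ev <- data.frame(capillary_id = events$capillary_id,
                   start_frame = events$start_frame - 1L,
                   end_frame = events$end_frame - 1L,
                   duration_frames = events$duration_frames,
                   duration_s = events$duration_s)
  write.csv(ev, paths["events"], row.names = FALSE, quote = FALSE)
  if (!is.null(statistics)) {
    paths["statistics"] <- file.path(out_dir, "statistics.json")
    jsonlite::write_json(unclass(statistics), paths["statistics"],
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(confusion)) {
    paths["confusion"] <- file.path(out_dir, "confusion.json")
    jsonlite::write_json(confusion_plain(confusion), paths["confusion"],
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Read a stallogram written by [write_results()]
#'
#' @param path `stallogram.csv` path.
#' @param frame_period Frame period, seconds.
#' @return A [stallogram()].
#' @export
read_stallogram_csv <- function(path, frame_period = 1 / 0.57) {
  df <- read.csv(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE]) == 1
  dimnames(mat) <- NULL
  stallogram(mat, df$capillary_id, frame_period)
}

#' Write simulator ground truth to a directory
#'
#' Writes `truth_stallogram.csv`, `truth_events.csv`, `centerlines.csv`
#' (`capillary_id, point_index, x_px, y_px`; 0-based, x = column,
#' y = row), and `truth.json` (motion offsets and, if present, arteriole
#' dynamics). All indices 0-based.
#'
#' @param truth The `truth` element of a [simulate_angiogram()] result.
#' @param out_dir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
write_ground_truth <- function(truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(stallogram = file.path(out_dir, "truth_stallogram.csv"),
             events = file.path(out_dir, "truth_events.csv"),
             centerlines = file.path(out_dir, "centerlines.csv"),
             json = file.path(out_dir, "truth.json"))
  write.csv(stallogram_to_df(truth$stallogram), paths["stallogram"],
            row.names = FALSE, quote = FALSE)
  ev <- truth$stall_events
  write.csv(data.frame(capillary_id = ev$capillary_id,
                       start_frame = ev$start_frame - 1L,
                       end_frame = ev$end_frame - 1L,
                       duration_frames = ev$duration_frames,
                       duration_s = ev$duration_s),
            paths["events"], row.names = FALSE, quote = FALSE)
  cls <- do.call(rbind, lapply(truth$centerlines, function(cl) {
    data.frame(capillary_id = cl$capillary_id,
               point_index = seq_len(cl$length_px) - 1L,
               x_px = cl$points[, 1] - 1,
               y_px = cl$points[, 2] - 1)
  }))
  write.csv(cls, paths["centerlines"], row.names = FALSE, quote = FALSE)
  meta <- list(motion_offsets_px = unname(truth$motion_offsets))
  if (!is.null(truth$artery)) {
    meta$artery <- list(diameter_um = truth$artery$diameter_um,
                        dff_true = truth$artery$dff_true,
                        peak_frames = truth$artery$peak_frames - 1L,
                        center_x_px = truth$artery$center_x_px - 1)
  }
  jsonlite::write_json(meta, paths["json"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read capillary selection clicks
#'
#' CSV schema: `capillary_label, x_px, y_px` — one row per selected
#' capillary, coordinates 0-based (x = column, y = row). The returned
#' data frame adds 1-based `x`, `y` columns for use with
#' [select_centerline()].
#'
#' @param path CSV path.
#' @return Data frame with `capillary_label`, `x_px`, `y_px`, `x`, `y`.
#' @export
read_clicks <- function(path) {
  df <- read.csv(path)
  need <- c("capillary_label", "x_px", "y_px")
  if (!all(need %in% names(df))) {
    stop("clicks file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$x <- df$x_px + 1
  df$y <- df$y_px + 1
  df
}
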