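## Reading and writing the pipeline's interchange formats: long-format
## midline CSV (shared by the generator and the tracker, so outputs can be
## diffed at file level), multi-page TIFF / numbered PNG frame stacks, and
## JSON metadata sidecars.

#' Write one or more midline sequences to a long-format CSV
#'
#' Columns: individual, treatment, regeneration_pct, trial, frame,
#' point_index, x_px, y_px. Coordinates are written in pixels (for
#' generated sequences in physical units, converted via `pixels_per_bl`).
#' A JSON sidecar (same path with extension `.json`) records frame rate,
#' pixel scale and the y-axis convention, so a sequence can be
#' reconstructed exactly.
#'
#' @param seqs a `midline_sequence` or list of them.
#' @param path output CSV path.
#' @param meta data.frame with one row per sequence and columns individual,
#'   treatment, regeneration_pct, trial (defaults are filled in if NULL).
#' @param pixels_per_bl pixel scale used when a sequence is in physical
#'   units.
#' @return `path`, invisibly.
#' @export
write_midline_csv <- function(seqs, path, meta = NULL, pixels_per_bl = 150) {
  if (inherits(seqs, "midline_sequence")) seqs <- list(seqs)
  if (is.null(meta))
    meta <- data.frame(individual = sprintf("ind%02d", seq_along(seqs)),
                       treatment = NA_character_,
                       regeneration_pct = NA_real_,
                       trial = 1L)
  stopifnot(nrow(meta) == length(seqs))
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    sq <- seqs[[i]]
    k <- if (sq$units == "px") 1 else pixels_per_bl / sq$scale
    np <- dim(sq$xy)[1]; nf <- dim(sq$xy)[3]
    y <- sq$xy[, 2, ] * k
    if (!isTRUE(sq$y_down)) y <- -y   # store in image convention
    rows[[i]] <- data.frame(individual = meta$individual[i],
                            treatment = meta$treatment[i],
                            regeneration_pct = meta$regeneration_pct[i],
                            trial = meta$trial[i],
                            frame = rep(seq_len(nf), each = np),
                            point_index = rep(seq_len(np), nf),
                            x_px = as.vector(sq$xy[, 1, ] * k),
                            y_px = as.vector(y))
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  side <- data.frame(individual = meta$individual, trial = meta$trial,
                     frame_rate_hz = vapply(seqs, `[[`, numeric(1),
                                            "frame_rate_hz"),
                     pixels_per_bl = vapply(seqs, function(sq)
                       if (sq$units == "px") sq$scale else pixels_per_bl,
                       numeric(1)))
  jsonlite::write_json(list(sequences = side, y_down = TRUE),
                       sub("\\.csv$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read midline sequences from a long-format CSV
#'
#' Inverse of [write_midline_csv()]. Sequences are keyed by (individual,
#' trial); frame rate and pixel scale come from the JSON sidecar unless
#' overridden.
#'
#' @param path CSV path.
#' @param frame_rate_hz override for the sidecar frame rate.
#' @return named list of `midline_sequence` objects (pixel units, image
#'   row-down convention) with an attribute `"meta"` table.
#' @export
read_midline_csv <- function(path, frame_rate_hz = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "trial", "frame", "point_index", "x_px", "y_px")
  if (!all(need %in% names(d)))
    stop("midline CSV must have columns ", paste(need, collapse = ", "))
  side_path <- sub("\\.csv$", ".json", path)
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path,
                                                          simplifyVector = TRUE)
          else NULL
  key <- interaction(d$individual, d$trial, drop = TRUE)
  out <- list(); meta <- list()
  for (k in levels(key)) {
    di <- d[key == k, ]
    di <- di[order(di$frame, di$point_index), ]
    np <- max(di$point_index); nf <- max(di$frame)
    fr <- frame_rate_hz
    ppbl <- NA_real_
    if (!is.null(side)) {
      row <- side$sequences[side$sequences$individual == di$individual[1] &
                            side$sequences$trial == di$trial[1], ]
      if (nrow(row) == 1) {
        if (is.null(fr)) fr <- row$frame_rate_hz
        ppbl <- row$pixels_per_bl
      }
    }
    if (is.null(fr)) stop("frame_rate_hz not given and no sidecar found")
    xy <- array(NA_real_, dim = c(np, 2, nf))
    xy[, 1, ] <- di$x_px; xy[, 2, ] <- di$y_px
    bl <- apply(xy, 3, function(m) sum(sqrt(rowSums(diff(m)^2))))
    sq <- structure(list(xy = xy, s = seq(0, 1, length.out = np),
                         time_s = (seq_len(nf) - 1) / fr,
                         frame_rate_hz = fr,
                         scale = if (is.finite(ppbl)) ppbl else mean(bl),
                         units = "px", y_down = TRUE,
                         body_length_px = bl, truth = NULL, params = NULL),
                    class = "midline_sequence")
    out[[k]] <- sq
    meta[[k]] <- di[1, c("individual", "treatment", "regeneration_pct",
                         "trial")]
  }
  attr(out, "meta") <- do.call(rbind, meta)
  out
}

#' Write a frame stack to disk
#'
#' Multi-page TIFF (`format = "tiff"`) or numbered 8-bit PNG frames in a
#' directory (`format = "png"`), plus a JSON sidecar echoing frame rate,
#' scale and per-frame window origins.
#'
#' @param stack a `frame_stack`.
#' @param path TIFF file path, or directory for PNG frames.
#' @param format "tiff" or "png".
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path, format = c("tiff", "png")) {
  format <- match.arg(format)
  norm <- lapply(stack$frames, function(m) {
    r <- range(m, 0, 1)
    (m - min(0, r[1])) / max(1, diff(r))
  })
  if (format == "tiff") {
    tiff::writeTIFF(norm, path, bits.per.sample = 8L)
    side <- sub("\\.tiff?$", ".json", path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (j in seq_along(norm))
      png::writePNG(norm[[j]], file.path(path, sprintf("frame%05d.png", j)))
    side <- file.path(path, "stack.json")
  }
  jsonlite::write_json(list(frame_rate_hz = stack$frame_rate_hz,
                            pixels_per_bl = stack$pixels_per_bl,
                            origin = stack$origin),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path TIFF file path or PNG directory.
#' @return a `frame_stack`-like list (without ground truth).
#' @export
read_frame_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    frames <- lapply(files, function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3) m <- m[, , 1]
      m
    })
    side <- file.path(path, "stack.json")
  } else {
    frames <- tiff::readTIFF(path, all = TRUE)
    frames <- lapply(frames, function(m) if (length(dim(m)) == 3) m[, , 1] else m)
    side <- sub("\\.tiff?$", ".json", path)
  }
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
          else stop("no JSON sidecar next to the frame stack")
  origin <- matrix(as.integer(meta$origin), ncol = 2)
  structure(list(frames = frames, origin = origin, truth_px = NULL,
                 frame_rate_hz = meta$frame_rate_hz,
                 pixels_per_bl = meta$pixels_per_bl,
                 spec = NULL, params = NULL),
            class = "frame_stack")
}
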