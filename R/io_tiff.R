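#' Construct a time-lapse dataset
#'
#' Container for one acquisition: an ordered list of frames, each a named
#' list of [voxel_grid()] objects (one per channel), sharing array shape and
#' spacing, with time indices consecutive from 0.
#'
#' @param frames list of frames; each frame a named list of `voxel_grid`s
#'   (names are channels, e.g. `nuclei`, `membranes`).
#' @param dt_seconds frame interval in seconds (> 0).
#' @return An object of class `timelapse_dataset`.
#' @export
timelapse_dataset <- function(frames, dt_seconds) {
  if (!length(frames)) stop("dataset must contain at least one frame", call. = FALSE)
  if (dt_seconds <= 0) stop("dt_seconds must be > 0", call. = FALSE)
  ch <- names(frames[[1]])
  d0 <- dim(frames[[1]][[1]]$values)
  sp0 <- frames[[1]][[1]]$spacing
  for (i in seq_along(frames)) {
    if (!identical(sort(names(frames[[i]])), sort(ch)))
      stop("all frames must carry the same channels", call. = FALSE)
    for (g in frames[[i]]) {
      if (!identical(dim(g$values), d0))
        stop(sprintf("frame %d shape (%s) differs from frame 0 shape (%s)",
                     i - 1L, paste(dim(g$values), collapse = "x"),
                     paste(d0, collapse = "x")), call. = FALSE)
      if (any(abs(g$spacing - sp0) > 1e-9))
        stop("all frames must share voxel spacing", call. = FALSE)
    }
  }
  structure(list(frames = frames, dt_seconds = dt_seconds,
                 spacing = sp0, channels = ch), class = "timelapse_dataset")
}

#' @export
print.timelapse_dataset <- function(x, ...) {
  d <- dim(x$frames[[1]][[1]]$values)
  cat(sprintf("<timelapse_dataset> %d frames (dt=%.3gs), channels: %s, %d x %d x %d voxels, spacing %s um\n",
              length(x$frames), x$dt_seconds, paste(x$channels, collapse = ", "),
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

# Read a single 3D TIFF stack as an array [z,y,x]; integer samples are
# returned unrescaled (as.is), float samples as stored.
.read_tiff_stack <- function(path) {
  info <- tiff::readTIFF(path, payload = FALSE)
  fmt <- attr(info, "sample.format")
  as_is <- is.null(fmt) || !identical(fmt, "float")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = as_is)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  arr <- array(0, c(length(pages), d2[1], d2[2]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  arr
}

#' Read a 3D+time TIFF series as a time-lapse dataset
#'
#' File naming uses a pattern with a `{t}` placeholder (and optionally
#' `{z}` for per-slice 2D series), e.g. `"embryo_t{t}.tif"`. Time indices
#' are discovered from matching files and must be consecutive; a literal
#' file name (no `{t}`) reads a single-frame dataset. Intensities are cast
#' to floating point without rescaling.
#'
#' @param pattern named character vector of patterns, one per channel (names
#'   `nuclei` / `membranes`), or a single unnamed pattern read as `nuclei`.
#' @param dir directory holding the files.
#' @param spacing voxel size `(sz, sy, sx)` in micrometres.
#' @param dt_seconds frame interval in seconds.
#' @return A [timelapse_dataset()].
#' @export
read_timelapse <- function(pattern, dir = ".", spacing, dt_seconds) {
  if (is.null(names(pattern))) names(pattern) <- rep("nuclei", length(pattern))
  per_channel <- lapply(names(pattern), function(chan) {
    pat <- pattern[[chan]]
    tok <- gsub("{z}", "\002", gsub("{t}", "\001", pat, fixed = TRUE), fixed = TRUE)
    esc <- gsub("([.|()^{}+$*?\\[\\]\\\\])", "\\\\\\1", tok)
    rx <- paste0("^", gsub("\002", "(\\d+)", gsub("\001", "(\\d+)", esc, fixed = TRUE),
                           fixed = TRUE), "$")
    files <- list.files(dir)
    m <- regmatches(files, regexec(rx, files))
    hit <- lengths(m) > 0
    if (!any(hit))
      stop(sprintf("no files in '%s' match pattern '%s'", dir, pat), call. = FALSE)
    files <- files[hit]
    has_z <- grepl("\\{z\\}", pat)
    has_t <- grepl("\\{t\\}", pat)
    # placeholder order as they appear in the pattern
    ph <- regmatches(pat, gregexpr("\\{[tz]\\}", pat))[[1]]
    caps <- do.call(rbind, lapply(m[hit], function(v) as.integer(v[-1])))
    if (!has_t) {
      if (length(files) != 1L && !has_z)
        stop("a pattern without {t} must match exactly one file", call. = FALSE)
      tvals <- rep(1L, length(files))
    } else tvals <- caps[, match("{t}", ph)]
    tu <- sort(unique(tvals))
    if (!identical(tu, seq.int(min(tu), max(tu))))
      stop(sprintf("missing frame index(es): %s",
                   paste(setdiff(seq.int(min(tu), max(tu)), tu), collapse = ", ")),
           call. = FALSE)
    grids <- vector("list", length(tu))
    for (k in seq_along(tu)) {
      tt <- tu[k]
      sel <- which(tvals == tt)
      if (has_z) {
        zvals <- caps[sel, match("{z}", ph)]
        sel <- sel[order(zvals)]
        slices <- lapply(file.path(dir, files[sel]), function(p) {
          a <- .read_tiff_stack(p)
          if (dim(a)[1] != 1L) stop("per-z series files must be single-page", call. = FALSE)
          a[1, , ]
        })
        d2 <- dim(slices[[1]])
        arr <- array(0, c(length(slices), d2[1], d2[2]))
        for (z in seq_along(slices)) arr[z, , ] <- slices[[z]]
      } else {
        arr <- .read_tiff_stack(file.path(dir, files[sel[1]]))
      }
      grids[[k]] <- voxel_grid(arr, spacing, t = tt - min(tu),
                               channel = if (chan == "membranes") "membranes" else "nuclei")
    }
    grids
  })
  names(per_channel) <- names(pattern)
  nt <- unique(vapply(per_channel, length, 1L))
  if (length(nt) != 1L) stop("channels cover different numbers of frames", call. = FALSE)
  frames <- lapply(seq_len(nt), function(k) lapply(per_channel, `[[`, k))
  timelapse_dataset(frames, dt_seconds)
}

#' Write a time-lapse dataset as multi-page TIFF stacks
#'
#' One file per frame and channel, named `<prefix>_<channel>_t%03d.tif`.
#' Integer-valued data in `[0, 65535]` is stored as 16-bit samples and
#' round-trips exactly through [read_timelapse()]; other data must lie in
#' `[0, 1]` and is stored as 32-bit float (or set `round_to_int = TRUE` to
#' quantize to 16-bit counts).
#'
#' @param dataset a [timelapse_dataset()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param round_to_int round intensities to integer counts before writing.
#' @return Character vector of files written, invisibly.
#' @export
write_timelapse <- function(dataset, dir, prefix = "stack", round_to_int = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (k in seq_along(dataset$frames)) {
    for (chan in names(dataset$frames[[k]])) {
      v <- dataset$frames[[k]][[chan]]$values
      if (round_to_int) v <- pmin(pmax(round(v), 0), 65535)
      pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ])
      path <- file.path(dir, sprintf("%s_%s_t%03d.tif", prefix, chan, k - 1L))
      if (all(v == round(v)) && min(v) >= 0 && max(v) <= 65535) {
        tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                        bits.per.sample = 16L, compression = "none", reduce = FALSE)
      } else if (min(v) >= 0 && max(v) <= 1) {
        tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                        compression = "none", reduce = FALSE)
      } else {
        stop("non-integer data outside [0,1]: use round_to_int = TRUE or rescale",
             call. = FALSE)
      }
      out <- c(out, path)
    }
  }
  invisible(out)
}
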