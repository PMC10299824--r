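# Track containers and delimited-text I/O.
#
# A track set holds many single-molecule trajectories as one long-format
# data frame (track_id, frame, x, y in micrometres) plus acquisition
# metadata. Coordinates are physical micrometres throughout: the 100 nm
# confined-jump threshold downstream is a physical length, so pixel-unit
# inputs must be converted at read time via `pixel_size_um`.

#' Construct a track set
#'
#' A `trackset` is the container for single-molecule trajectories: a
#' long-format table with one localization per row, sorted canonically by
#' track identifier and frame, plus the frame interval of the acquisition.
#'
#' @param tracks data frame with columns `track_id`, `frame`, `x`, `y`.
#'   Coordinates are in micrometres; frames are non-negative integers.
#'   Frames may be non-contiguous (linking gaps); a track's *duration* is
#'   its number of localizations, not its frame span.
#' @param frame_interval_s seconds per frame; default 0.01 (100 Hz
#'   acquisition, 10 ms exposure).
#' @param condition optional free-text condition label.
#' @param cell_id optional cell label.
#' @return An object of class `trackset`.
#' @examples
#' ts <- trackset(data.frame(track_id = "t1", frame = 0:2,
#'                           x = c(0, 0.1, 0.2), y = 0))
#' n_tracks(ts)
#' @export
trackset <- function(tracks = data.frame(track_id = character(), frame = integer(),
                                         x = double(), y = double()),
                     frame_interval_s = 0.01, condition = NULL, cell_id = NULL) {
  stopifnot(is.data.frame(tracks))
  need <- c("track_id", "frame", "x", "y")
  miss <- setdiff(need, names(tracks))
  if (length(miss))
    abort_format(sprintf("trackset is missing column(s): %s", paste(miss, collapse = ", ")))
  tracks <- tracks[need]
  tracks$track_id <- as.character(tracks$track_id)
  tracks$frame <- as.integer(tracks$frame)
  tracks$x <- as.double(tracks$x)
  tracks$y <- as.double(tracks$y)
  if (nrow(tracks)) {
    if (anyNA(tracks$frame) || any(tracks$frame < 0L))
      abort_validation("frame indices must be non-negative integers")
    if (!all(is.finite(tracks$x)) || !all(is.finite(tracks$y)))
      abort_validation("coordinates must be finite")
    if (anyDuplicated(tracks[c("track_id", "frame")]))
      abort_validation("duplicate (track_id, frame) pair in trackset")
    tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
    rownames(tracks) <- NULL
  }
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      !is.finite(frame_interval_s) || frame_interval_s <= 0)
    abort_validation("frame_interval_s must be a single positive number")
  structure(
    list(tracks = tracks, frame_interval_s = as.double(frame_interval_s),
         condition = condition, cell_id = cell_id),
    class = "trackset"
  )
}

#' Number of tracks in a track set
#' @param ts a [trackset()].
#' @return integer count of distinct tracks.
#' @export
n_tracks <- function(ts) {
  stopifnot(inherits(ts, "trackset"))
  length(unique(ts$tracks$track_id))
}

#' Per-track durations (number of localizations)
#' @param ts a [trackset()].
#' @return named integer vector, one entry per track.
#' @export
track_durations <- function(ts) {
  stopifnot(inherits(ts, "trackset"))
  if (!nrow(ts$tracks)) return(setNames(integer(), character()))
  tab <- table(ts$tracks$track_id)
  setNames(as.integer(tab), names(tab))
}

# Split into a named list of per-track data frames (frame, x, y), frame-sorted.
split_tracks <- function(ts) {
  stopifnot(inherits(ts, "trackset"))
  if (!nrow(ts$tracks)) return(list())
  split(ts$tracks[c("frame", "x", "y")], ts$tracks$track_id)
}

#' @export
print.trackset <- function(x, ...) {
  cat(sprintf("<trackset> %d tracks, %d localizations, frame interval %g s\n",
              n_tracks(x), nrow(x$tracks), x$frame_interval_s))
  if (!is.null(x$condition)) cat("  condition:", x$condition, "\n")
  if (!is.null(x$cell_id)) cat("  cell:", x$cell_id, "\n")
  invisible(x)
}

#' @export
format.trackset <- function(x, ...) {
  sprintf("<trackset: %d tracks>", n_tracks(x))
}

#' @export
as.data.frame.trackset <- function(x, ...) x$tracks

# "# key=value" comment lines at the top of a track table
parse_header_meta <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  meta <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !grepl("^\\s*#", line)) break
    m <- regmatches(line, regexec("^\\s*#\\s*([A-Za-z_]+)=(.*)$", line))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  meta
}

default_track_dialect <- function() {
  list(track_id = "track_id", frame = "frame", x = "x_um", y = "y_um")
}

# Sniff comma vs tab from the first non-comment line.
detect_delim <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) return(",")
    if (!grepl("^\\s*#", line) && nzchar(trimws(line))) break
  }
  if (lengths(regmatches(line, gregexpr("\t", line))) >=
      lengths(regmatches(line, gregexpr(",", line)))) "\t" else ","
}

#' Read a track table
#'
#' Reads a delimited text table of single-molecule localizations (one row
#' per localization) into a [trackset()]. The delimiter (comma or tab) is
#' auto-detected and lines starting with `#` are ignored. Input rows need
#' not be sorted; localizations are frame-sorted within each track and
#' tracks ordered by identifier.
#'
#' @param path file path.
#' @param dialect named list mapping the roles `track_id`, `frame`, `x`, `y`
#'   to column names in the file. Defaults to
#'   `track_id`, `frame`, `x_um`, `y_um`.
#' @param pixel_size_um if the file stores coordinates in pixels, the pixel
#'   size in micrometres; coordinates are multiplied by it. `NULL` (default)
#'   means coordinates are already micrometres.
#' @param frame_interval_s,condition,cell_id metadata passed to [trackset()].
#' @return A [trackset()].
#' @export
read_track_table <- function(path, dialect = default_track_dialect(),
                             pixel_size_um = NULL, frame_interval_s = 0.01,
                             condition = NULL, cell_id = NULL) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  dialect <- modifyList(default_track_dialect(), as.list(dialect))
  # header comments may carry metadata written by write_track_table; they are
  # used only where the caller did not supply the argument
  meta <- parse_header_meta(path)
  if (missing(frame_interval_s) && !is.null(meta$frame_interval_s))
    frame_interval_s <- as.numeric(meta$frame_interval_s)
  if (missing(condition) && !is.null(meta$condition)) condition <- meta$condition
  if (missing(cell_id) && !is.null(meta$cell_id)) cell_id <- meta$cell_id
  delim <- detect_delim(path)
  df <- read.delim(path, sep = delim, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  for (role in c("track_id", "frame", "x", "y")) {
    col <- dialect[[role]]
    if (!col %in% names(df))
      abort_format(sprintf("required column '%s' (role %s) not found in %s",
                           col, role, path))
  }
  out <- data.frame(track_id = df[[dialect$track_id]], stringsAsFactors = FALSE)
  for (role in c("frame", "x", "y")) {
    raw <- df[[dialect[[role]]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & nzchar(trimws(raw)))
    if (anyNA(val)) {
      row <- if (length(bad)) bad[1L] else which(is.na(val))[1L]
      abort_format(sprintf("non-numeric value '%s' in column '%s', data row %d",
                           raw[row], dialect[[role]], row))
    }
    out[[role]] <- val
  }
  if (!is.null(pixel_size_um)) {
    stopifnot(is.numeric(pixel_size_um), pixel_size_um > 0)
    out$x <- out$x * pixel_size_um
    out$y <- out$y * pixel_size_um
  }
  if (nrow(out) && anyDuplicated(out[c("track_id", "frame")])) {
    d <- out[duplicated(out[c("track_id", "frame")]), ][1L, ]
    abort_format(sprintf("duplicate localization for track '%s' at frame %d",
                         d$track_id, as.integer(d$frame)))
  }
  trackset(out, frame_interval_s = frame_interval_s,
           condition = condition, cell_id = cell_id)
}

#' Write a track table
#'
#' Writes a [trackset()] as comma-delimited text with the default column
#' schema `track_id,frame,x_um,y_um`, preceded by `#`-prefixed provenance
#' comment lines. Coordinates are written with full precision so that
#' `read_track_table(write_track_table(ts))` reproduces `ts`.
#'
#' @param ts a [trackset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(ts, path) {
  stopifnot(inherits(ts, "trackset"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort_format(sprintf("cannot write to '%s'", path)))
  on.exit(close(con))
  writeLines(c(
    sprintf("# mobprox track table (%d tracks)", n_tracks(ts)),
    sprintf("# frame_interval_s=%.17g", ts$frame_interval_s),
    if (!is.null(ts$condition)) sprintf("# condition=%s", ts$condition),
    if (!is.null(ts$cell_id)) sprintf("# cell_id=%s", ts$cell_id)
  ), con)
  df <- ts$tracks
  out <- data.frame(track_id = df$track_id, frame = df$frame,
                    x_um = sprintf("%.17g", df$x), y_um = sprintf("%.17g", df$y))
  write.table(out, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
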