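#' Construct a set of cell tracks for one imaging field
#'
#' A `track_set` bundles the time-ordered centroid positions of every tracked
#' cell in one field with the metadata needed downstream: treatment condition,
#' knockdown label, replicate, field geometry and the acquisition interval.
#'
#' @param tracks data.frame with columns `track_id`, `frame`, `x`, `y`
#'   (a `t` column in minutes is recomputed as `frame * frame_interval`).
#'   Coordinates are pixels, origin top-left, y increasing downward, frames
#'   0-based.
#' @param field_id identifier of the imaging field.
#' @param condition treatment label (e.g. `"EGF"`, `"OSM"`, `"IFNG+EGF"`).
#' @param knockdown knockdown label, or `NA` for untransfected fields.
#' @param replicate integer biological replicate.
#' @param field_width,field_height field extent in pixels.
#' @param frame_interval minutes between frames (default 30).
#' @return An object of class `track_set`.
#' @export
track_set <- function(tracks, field_id = "field1", condition = NA_character_,
                      knockdown = NA_character_, replicate = 1L,
                      field_width = 1000, field_height = 1000,
                      frame_interval = 30) {
  stopifnot(is.data.frame(tracks))
  needed <- c("track_id", "frame", "x", "y")
  missing_cols <- setdiff(needed, names(tracks))
  if (length(missing_cols) > 0L) {
    stop("tracks is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  tracks <- tracks[, needed, drop = FALSE]
  tracks$track_id <- as.character(tracks$track_id)
  tracks$frame <- as.integer(tracks$frame)
  bad <- !is.finite(tracks$x) | !is.finite(tracks$y)
  if (any(bad)) stop("non-finite coordinates in tracks; drop them before construction")
  if (any(tracks$frame < 0L)) stop("frames must be non-negative")
  dup <- duplicated(tracks[, c("track_id", "frame")])
  if (any(dup)) {
    d <- tracks[dup, , drop = FALSE][1L, ]
    stop(sprintf("duplicated (track_id, frame) pair: ('%s', %d)",
                 d$track_id, d$frame))
  }
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  tracks$t <- tracks$frame * frame_interval
  tracks <- tracks[, c("track_id", "frame", "t", "x", "y")]
  structure(
    list(tracks = tracks, field_id = field_id, condition = condition,
         knockdown = knockdown, replicate = as.integer(replicate),
         field_width = field_width, field_height = field_height,
         frame_interval = frame_interval),
    class = "track_set"
  )
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf(
    "<track_set> field '%s' | condition %s | knockdown %s | replicate %d\n",
    x$field_id, x$condition, x$knockdown, x$replicate))
  cat(sprintf("  %d tracks, %d observations, frames %d..%d (dt = %g min), field %gx%g px\n",
              length(unique(x$tracks$track_id)), nrow(x$tracks),
              min(x$tracks$frame), max(x$tracks$frame),
              x$frame_interval, x$field_width, x$field_height))
  invisible(x)
}

#' Number of tracks in a track set
#' @param x a `track_set`.
#' @return integer count of distinct track ids.
#' @export
n_tracks <- function(x) length(unique(x$tracks$track_id))

# canonical column names a schema_map may rename to
.track_cols <- c("track_id", "frame", "x", "y")

# built-in header dialects accepted without an explicit schema_map
.track_dialects <- list(
  c(track_id = "track_id", frame = "frame", x = "x", y = "y"),
  c(track_id = "id", frame = "frame", x = "x", y = "y"),
  c(track_id = "track_id", frame = "position_t", x = "position_x", y = "position_y")
)

#' Read cell-track tables
#'
#' Reads a delimited track table (comma by default, tab accepted) with
#' '#'-prefixed metadata header lines, and returns one [track_set()] per
#' (field, condition, knockdown, replicate) group. Rows with non-finite
#' coordinates are dropped and counted in the attached log.
#'
#' @param path file path.
#' @param schema_map named character vector mapping canonical names
#'   (`track_id`, `frame`, `x`, `y`, and optionally `field_id`, `condition`,
#'   `knockdown`, `replicate`) to the file's column headers. When `NULL`,
#'   common tracker dialects (`id`/`frame`/`x`/`y`,
#'   `position_t`/`position_x`/`position_y`) are tried.
#' @param field_width,field_height,frame_interval defaults used when the file
#'   header does not record them.
#' @return list of `track_set` objects; attribute `"log"` records dropped rows.
#' @export
read_tracks <- function(path, schema_map = NULL,
                        field_width = 1000, field_height = 1000,
                        frame_interval = 30) {
  if (!file.exists(path)) stop("no such file: ", path)
  header_meta <- .read_hash_header(path)
  if (!is.null(header_meta$field_width)) field_width <- as.numeric(header_meta$field_width)
  if (!is.null(header_meta$field_height)) field_height <- as.numeric(header_meta$field_height)
  if (!is.null(header_meta$frame_interval)) frame_interval <- as.numeric(header_meta$frame_interval)

  first_data <- .first_noncomment_line(path)
  sep <- if (grepl("\t", first_data)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)

  if (is.null(schema_map)) {
    hit <- NULL
    for (d in .track_dialects) {
      if (all(d %in% names(df))) { hit <- d; break }
    }
    if (is.null(hit)) {
      stop("could not match columns ", paste(names(df), collapse = ", "),
           " to a known track dialect; missing mandatory column(s): ",
           paste(setdiff(.track_cols, names(df)), collapse = ", "),
           " (supply schema_map)")
    }
    schema_map <- hit
  }
  miss <- setdiff(.track_cols, names(schema_map))
  if (length(miss) > 0L) stop("schema_map missing mandatory column(s): ",
                              paste(miss, collapse = ", "))
  absent <- schema_map[!schema_map %in% names(df)]
  if (length(absent) > 0L) stop("file is missing mandatory column(s): ",
                                paste(absent, collapse = ", "))
  out <- data.frame(track_id = as.character(df[[schema_map[["track_id"]]]]),
                    frame = as.integer(df[[schema_map[["frame"]]]]),
                    x = as.numeric(df[[schema_map[["x"]]]]),
                    y = as.numeric(df[[schema_map[["y"]]]]),
                    stringsAsFactors = FALSE)
  grouping <- list()
  for (g in c("field_id", "condition", "knockdown", "replicate")) {
    src <- if (g %in% names(schema_map)) schema_map[[g]] else g
    if (src %in% names(df)) {
      grouping[[g]] <- df[[src]]
    } else if (!is.null(header_meta[[g]])) {
      grouping[[g]] <- rep(header_meta[[g]], nrow(df))
    }
  }
  bad <- !is.finite(out$x) | !is.finite(out$y)
  n_dropped <- sum(bad)
  if (n_dropped > 0L) {
    out <- out[!bad, , drop = FALSE]
    grouping <- lapply(grouping, function(v) v[!bad])
  }

  key <- if (length(grouping) == 0L) rep("all", nrow(out)) else
    do.call(paste, c(grouping, sep = "\r"))
  sets <- lapply(split(seq_len(nrow(out)), key), function(idx) {
    meta <- lapply(grouping, function(v) v[idx[1L]])
    track_set(out[idx, , drop = FALSE],
              field_id = if (is.null(meta$field_id)) basename(path) else meta$field_id,
              condition = if (is.null(meta$condition)) NA_character_ else meta$condition,
              knockdown = if (is.null(meta$knockdown)) NA_character_ else meta$knockdown,
              replicate = if (is.null(meta$replicate)) 1L else as.integer(meta$replicate),
              field_width = field_width, field_height = field_height,
              frame_interval = frame_interval)
  })
  names(sets) <- NULL
  attr(sets, "log") <- list(n_rows_read = nrow(df), n_dropped_nonfinite = n_dropped)
  sets
}

#' Write a track set to a delimited file
#'
#' Canonical column order (`track_id`, `frame`, `t`, `x`, `y`), '#'-prefixed
#' metadata header lines, fixed 6-decimal coordinate precision so that
#' write-then-read is exact.
#'
#' @param trackset a [track_set()].
#' @param path output path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_tracks <- function(trackset, path, sep = ",") {
  stopifnot(inherits(trackset, "track_set"))
  meta <- c(field_id = trackset$field_id, condition = trackset$condition,
            knockdown = trackset$knockdown, replicate = trackset$replicate,
            field_width = trackset$field_width,
            field_height = trackset$field_height,
            frame_interval = trackset$frame_interval)
  hdr <- sprintf("# %s: %s", names(meta), as.character(meta))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- trackset$tracks
  df$x <- sprintf("%.6f", df$x)
  df$y <- sprintf("%.6f", df$y)
  df$t <- sprintf("%g", df$t)
  writeLines(paste(c("track_id", "frame", "t", "x", "y"), collapse = sep), con)
  if (nrow(df) > 0L) {
    writeLines(do.call(paste, c(df[c("track_id", "frame", "t", "x", "y")],
                                sep = sep)), con)
  }
  invisible(path)
}

#' Validate a track set
#'
#' Report-only quality check: lists out-of-bounds points, per-track frame
#' gaps, and zero-length (single-observation) tracks. Never mutates input.
#'
#' @param trackset a [track_set()].
#' @return list with data.frames `out_of_bounds`, `gaps`, and character vector
#'   `zero_length`; all empty on a clean set.
#' @export
validate_tracks <- function(trackset) {
  stopifnot(inherits(trackset, "track_set"))
  tr <- trackset$tracks
  oob <- tr[tr$x < 0 | tr$x > trackset$field_width |
            tr$y < 0 | tr$y > trackset$field_height, , drop = FALSE]
  gaps <- do.call(rbind, lapply(split(tr$frame, tr$track_id), function(fr) {
    fr <- sort(fr)
    d <- diff(fr)
    if (all(d == 1L) || length(fr) < 2L) return(NULL)
    idx <- which(d > 1L)
    data.frame(after_frame = fr[idx], before_frame = fr[idx + 1L],
               n_missing = d[idx] - 1L)
  }))
  if (!is.null(gaps) && nrow(gaps) > 0L) {
    ids <- rep(names(split(tr$frame, tr$track_id)),
               vapply(split(tr$frame, tr$track_id), function(fr) {
                 fr <- sort(fr); if (length(fr) < 2L) 0L else sum(diff(fr) > 1L)
               }, integer(1)))
    gaps <- cbind(track_id = ids, gaps)
    rownames(gaps) <- NULL
  } else {
    gaps <- data.frame(track_id = character(0), after_frame = integer(0),
                       before_frame = integer(0), n_missing = integer(0))
  }
  lens <- table(tr$track_id)
  list(out_of_bounds = oob,
       gaps = gaps,
       zero_length = names(lens)[lens == 1L])
}

# ---- internal helpers ----

.read_hash_header <- function(path) {
  lines <- readLines(path, n = 100L, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  out <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) out[[trimws(m[2])]] <- trimws(m[3])
  }
  out
}

.first_noncomment_line <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1L, warn = FALSE)
    if (length(l) == 0L) return("")
    if (!grepl("^#", l)) return(l)
  }
}
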