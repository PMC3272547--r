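#' Track tables
#'
#' The exchange container shared by the simulator, the synthetic
#' generators and every statistic is a *track set*: a data frame with
#' columns `track_id` (character), `t` (minutes, strictly increasing
#' within a track), `x`, `y` (micrometres) and `group` (character), plus
#' an optional logical `arrived` column written by the simulator. Free
#' metadata (attractant source, cluster centroid, partner direction,
#' ...) travels in the `"metadata"` attribute.
#'
#' @param data data frame with at least `track_id`, `t`, `x`, `y`;
#'   missing `group` defaults to `"1"`.
#' @param metadata named list of free-form annotations.
#' @return A data frame of class `c("track_set", "data.frame")`, sorted
#'   by track then time.
#' @export
track_set <- function(data, metadata = list()) {
  req <- c("track_id", "t", "x", "y")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0L) {
    stop("missing track columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(data$group)) data$group <- rep("1", nrow(data))
  data$track_id <- as.character(data$track_id)
  data$group <- as.character(data$group)
  for (col in c("t", "x", "y")) {
    v <- suppressWarnings(as.numeric(data[[col]]))
    bad <- which(is.na(v) & !is.na(data[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric or non-finite `%s` in row %d",
                   col, bad[1L]), call. = FALSE)
    }
    data[[col]] <- v
  }
  data <- data[order(data$track_id, data$t), , drop = FALSE]
  rownames(data) <- NULL
  key <- paste(data$track_id, data$t)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicated (track_id, t) at row %d",
                 which(duplicated(key))[1L]), call. = FALSE)
  }
  structure(data,
            metadata = metadata,
            class = c("track_set", "data.frame"))
}

#' Split a track set into per-track coordinate matrices
#'
#' @param tracks a [track_set()].
#' @return Named list, one element per track: list with `id`, `times`,
#'   `positions` (n x 2 matrix) and `group`.
#' @export
split_tracks <- function(tracks) {
  idx <- split(seq_len(nrow(tracks)), tracks$track_id)
  lapply(idx, function(i) {
    list(id = tracks$track_id[i[1L]],
         times = tracks$t[i],
         positions = cbind(x = tracks$x[i], y = tracks$y[i]),
         group = tracks$group[i[1L]])
  })
}

#' @rdname track_set
#' @param x a `track_set`.
#' @export
track_metadata <- function(x) attr(x, "metadata") %||% list()

#' Read a track CSV
#'
#' Reads the documented track schema: header
#' `track_id,t,x,y,group[,arrived]`, UTF-8, `.` decimal separator. Rows
#' are validated (numeric coordinates, strictly increasing time and no
#' duplicated time point within a track) and sorted by track then time.
#'
#' @param path file to read.
#' @return A [track_set()].
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(track_id = "character"))
  ts <- track_set(df)
  if (!is.null(ts$arrived)) ts$arrived <- as.logical(ts$arrived)
  ts
}

#' Write a track CSV
#'
#' Deterministic inverse of [read_tracks()]: rows ordered by track id
#' then time, full numeric precision, no row names.
#'
#' @param tracks a [track_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  if (nrow(tracks) > 0L &&
      !all(is.finite(tracks$x) & is.finite(tracks$y) & is.finite(tracks$t))) {
    stop("non-finite coordinates cannot be written", call. = FALSE)
  }
  cols <- intersect(c("track_id", "t", "x", "y", "group", "arrived"),
                    names(tracks))
  utils::write.csv(as.data.frame(tracks)[, cols, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
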