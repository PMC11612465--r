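#' Combined speed from velocity components
#'
#' Magnitude of the planar velocity, `sqrt(speed_x^2 + speed_y^2)`, in
#' px/frame. In the tracked tables speed-x is stored as a magnitude and
#' speed-y keeps its sign; both conventions feed through unchanged.
#'
#' @param speed_x,speed_y velocity components, px/frame; recycled to a common
#'   length.
#' @return Combined speed, px/frame.
#' @examples
#' combined_speed(7, -8)      # 10.63 at 2 dp
#' combined_speed(29.5, -2)   # 29.57 at 2 dp
#' @export
combined_speed <- function(speed_x, speed_y) {
  if (!all(is.finite(speed_x)) || !all(is.finite(speed_y)))
    stop("speed components must be finite")
  sqrt(speed_x^2 + speed_y^2)
}

#' Finite-difference velocities along a track
#'
#' Per-step displacement divided by the (constant) frame gap. The first
#' sample, which has no preceding interval, is backfilled with the second
#' sample's velocity so the velocity array stays frame-aligned.
#'
#' @param positions matrix or data.frame with columns x, y, ordered by frame.
#' @param frame_gap frames between consecutive samples.
#' @return Matrix with columns `vx`, `vy`, one row per input position.
#' @export
finite_difference_velocity <- function(positions, frame_gap = 1) {
  p <- as.matrix(positions)[, 1:2, drop = FALSE]
  if (nrow(p) < 2) stop("need at least 2 positions to differentiate")
  stopifnot(frame_gap > 0)
  v <- diff(p) / frame_gap
  v <- rbind(v[1, , drop = FALSE], v)
  colnames(v) <- c("vx", "vy")
  v
}

# canonical frame-table column order (tracked-table schema)
frame_table_cols <- c("number", "x", "y", "speed_x", "speed_y", "speed", "frame")

#' Assemble a frame-table data frame
#'
#' A frame table holds one row per fish per frame with the tracked-table
#' schema: `number`, `x`, `y`, `speed_x` (magnitude), `speed_y` (signed),
#' `speed` (combined magnitude), `frame`.
#'
#' @param number,x,y,speed_x,speed_y,speed,frame column vectors.
#' @return A `data.frame` with class `frame_table`.
#' @export
frame_table <- function(number, x, y, speed_x, speed_y,
                        speed = combined_speed(speed_x, speed_y), frame = 1L) {
  df <- data.frame(number = as.integer(number), x = x, y = y,
                   speed_x = speed_x, speed_y = speed_y, speed = speed,
                   frame = as.integer(frame))
  validate_frame_table(df)
}

validate_frame_table <- function(df, where = "frame table") {
  missing <- setdiff(frame_table_cols, names(df))
  if (length(missing))
    stop(where, " missing columns: ", paste(missing, collapse = ", "))
  df <- df[frame_table_cols]
  dup <- duplicated(df[c("frame", "number")])
  if (any(dup))
    stop(where, ": duplicate fish id within a frame at row(s) ",
         paste(which(dup), collapse = ", "))
  class(df) <- c("frame_table", "data.frame")
  df
}

#' Flag anomalous rows in a frame table
#'
#' A row is anomalous when its recorded combined speed is inconsistent with
#' its components (difference above `tol` after 2-decimal rounding) or when a
#' component exceeds `max_speed`. Such rows occur in tracker output (a fish
#' can be mis-associated between frames, producing absurd per-frame
#' displacements) and must be excluded from region averages.
#'
#' @param table a frame-table data frame.
#' @param tol speed-consistency tolerance after 2-dp rounding, px/frame.
#' @param max_speed largest plausible component magnitude, px/frame.
#' @return data.frame with columns `frame`, `number`, `reason` (zero rows if
#'   clean).
#' @export
flag_anomalies <- function(table, tol = 0.01, max_speed = 100) {
  table <- validate_frame_table(table)
  recomputed <- round(combined_speed(table$speed_x, table$speed_y), 2)
  inconsistent <- abs(recomputed - table$speed) > tol
  too_fast <- abs(table$speed_x) > max_speed | abs(table$speed_y) > max_speed
  reason <- ifelse(inconsistent & too_fast, "speed_mismatch;component_over_max",
            ifelse(inconsistent, "speed_mismatch",
            ifelse(too_fast, "component_over_max", NA)))
  bad <- !is.na(reason)
  data.frame(frame = table$frame[bad], number = table$number[bad],
             reason = reason[bad])
}

#' Drop flagged rows from a frame table
#'
#' @inheritParams flag_anomalies
#' @param ... passed to [flag_anomalies()].
#' @export
clean_frame_table <- function(table, ...) {
  table <- validate_frame_table(table)
  flags <- flag_anomalies(table, ...)
  if (nrow(flags) == 0) return(table)
  key <- paste(table$frame, table$number)
  table[!key %in% paste(flags$frame, flags$number), , drop = FALSE]
}

#' Read frame tables from CSV
#'
#' Expects the tracked-table schema
#' (`number,x,y,speed_x,speed_y,speed,frame`); extra columns are dropped.
#'
#' @param path CSV path.
#' @return A `frame_table` data frame spanning all frames in the file.
#' @export
read_frame_tables <- function(path) {
  if (!file.exists(path)) stop("frame table file not found: ", path)
  df <- utils::read.csv(path, check.names = TRUE)
  validate_frame_table(df, where = path)
}

#' Write frame tables to CSV
#'
#' Values are serialized at 2 decimals, the precision of the tracked tables;
#' a write/read round trip is lossless at that precision.
#'
#' @param table a frame-table data frame.
#' @param path output CSV path.
#' @export
write_frame_tables <- function(table, path) {
  table <- validate_frame_table(table)
  out <- table
  for (col in c("x", "y", "speed_x", "speed_y", "speed"))
    out[[col]] <- round(out[[col]], 2)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# split a frame table into per-frame chunks (list named by frame)
split_frames <- function(table) {
  split(as.data.frame(table), table$frame)
}
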