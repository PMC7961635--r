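# Readers and writers for the tab-delimited motion-capture formats of
# the OpenSim ecosystem: TRC (marker trajectories), STO/MOT (generic
# time series) and a flat quaternion CSV for orientation streams.
# Round trips are value-identical; header bookkeeping is validated.

#' Write marker trajectories to TRC
#'
#' @param frames list of [observation_frame()]s with markers.
#' @param path output path.
#' @param fs sampling rate written to the header (inferred from
#'   timestamps when `NULL`).
#' @param units length units string.
#' @return `path`, invisibly.
#' @export
write_trc <- function(frames, path, fs = NULL, units = "m") {
  marker_names <- names(frames[[1]]$markers)
  times <- vapply(frames, function(f) f$t, numeric(1))
  if (is.null(fs)) fs <- 1 / stats::median(diff(times))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("PathFileType", "4", "(X/Y/Z)", basename(path),
                   sep = "\t"), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units", "OrigDataRate", "OrigDataStartFrame",
                   "OrigNumFrames", sep = "\t"), con)
  writeLines(paste(fs, fs, length(frames), length(marker_names), units,
                   fs, 1, length(frames), sep = "\t"), con)
  head1 <- c("Frame#", "Time",
             unlist(lapply(marker_names, function(m) c(m, "", ""))))
  writeLines(paste(head1, collapse = "\t"), con)
  head2 <- c("", "", unlist(lapply(seq_along(marker_names), function(i)
    paste0(c("X", "Y", "Z"), i))))
  writeLines(paste(head2, collapse = "\t"), con)
  writeLines("", con)
  for (i in seq_along(frames)) {
    row <- c(i, format(times[i], digits = 12))
    for (m in marker_names) {
      p <- frames[[i]]$markers[[m]]
      row <- c(row, if (is.null(p)) c("", "", "")
               else format(p, digits = 12))
    }
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read marker trajectories from TRC
#'
#' @param path TRC file path.
#' @return list of [observation_frame()]s (occluded markers are `NULL`).
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (!grepl("^PathFileType", lines[1])) stop("not a TRC file: ", path)
  meta_names <- strsplit(lines[2], "\t")[[1]]
  meta_vals <- strsplit(lines[3], "\t")[[1]]
  meta <- stats::setNames(as.list(meta_vals), meta_names)
  n_markers <- as.integer(meta$NumMarkers)
  n_frames <- as.integer(meta$NumFrames)
  head1 <- strsplit(lines[4], "\t")[[1]]
  marker_names <- head1[seq(3, by = 3, length.out = n_markers)]
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_frames)
    stop("TRC header declares ", n_frames, " frames but body has ",
         length(body))
  lapply(body, function(ln) {
    fields <- strsplit(ln, "\t")[[1]]
    t <- as.numeric(fields[2])
    mk <- stats::setNames(vector("list", n_markers), marker_names)
    for (i in seq_len(n_markers)) {
      v <- fields[3 * i + 0:2]
      v <- suppressWarnings(as.numeric(v))
      mk[[i]] <- if (length(v) < 3 || any(is.na(v))) NULL else v
    }
    observation_frame(t, markers = mk)
  })
}

#' Write a time-series table to STO/MOT
#'
#' @param df data.frame whose first column is `time`.
#' @param path output path.
#' @param name dataset name written in the header.
#' @param in_degrees whether angle columns are in degrees.
#' @return `path`, invisibly.
#' @export
write_sto <- function(df, path, name = basename(path),
                      in_degrees = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(name, con)
  writeLines("version=1", con)
  writeLines(paste0("nRows=", nrow(df)), con)
  writeLines(paste0("nColumns=", ncol(df)), con)
  writeLines(paste0("inDegrees=", if (in_degrees) "yes" else "no"), con)
  writeLines("endheader", con)
  writeLines(paste(names(df), collapse = "\t"), con)
  utils::write.table(format(df, digits = 12, trim = TRUE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read an STO/MOT time-series table
#'
#' @param path file path.
#' @return data.frame; attribute `in_degrees` records the header flag.
#' @export
read_sto <- function(path) {
  lines <- readLines(path)
  end <- which(trimws(lines) == "endheader")
  if (length(end) != 1) stop("malformed STO/MOT header (no endheader): ",
                             path)
  header <- lines[seq_len(end - 1)]
  get_field <- function(key) {
    hit <- grep(paste0("^", key, "="), header, value = TRUE)
    if (length(hit) == 0) return(NA)
    sub(paste0("^", key, "="), "", hit[1])
  }
  n_rows <- as.integer(get_field("nRows"))
  n_cols <- as.integer(get_field("nColumns"))
  cols <- strsplit(lines[end + 1], "\t")[[1]]
  body <- lines[-(seq_len(end + 1))]
  body <- body[nzchar(trimws(body))]
  if (!is.na(n_rows) && length(body) != n_rows)
    stop("STO header declares nRows=", n_rows, " but body has ",
         length(body), " rows")
  if (!is.na(n_cols) && length(cols) != n_cols)
    stop("STO header declares nColumns=", n_cols, " but found ",
         length(cols), " column names")
  df <- utils::read.table(text = body, sep = "\t",
                          col.names = cols, check.names = FALSE)
  attr(df, "in_degrees") <- identical(get_field("inDegrees"), "yes")
  df
}

#' Write orientation streams to a quaternion CSV
#'
#' Columns: `time`, then `<name>_w, <name>_x, <name>_y, <name>_z` per
#' sensor.
#'
#' @param frames list of [observation_frame()]s with orientations.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quat_csv <- function(frames, path) {
  sensor_names <- names(frames[[1]]$orientations)
  rows <- lapply(frames, function(f) {
    vals <- unlist(lapply(sensor_names, function(s) {
      q <- f$orientations[[s]]
      if (is.null(q)) rep(NA_real_, 4) else q
    }))
    c(f$t, vals)
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("time", unlist(lapply(sensor_names, function(s)
    paste0(s, "_", c("w", "x", "y", "z")))))
  utils::write.csv(format(df, digits = 12, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a quaternion CSV orientation stream
#'
#' @param path file path.
#' @return list of [observation_frame()]s.
#' @export
read_quat_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time") stop("quaternion CSV must start with 'time'")
  qcols <- names(df)[-1]
  sensors <- unique(sub("_[wxyz]$", "", qcols))
  lapply(seq_len(nrow(df)), function(i) {
    ors <- stats::setNames(lapply(sensors, function(s) {
      q <- as.numeric(df[i, paste0(s, "_", c("w", "x", "y", "z"))])
      if (any(is.na(q))) NULL else quat_normalize(q)
    }), sensors)
    observation_frame(df$time[i], orientations = ors)
  })
}

#' Convert a generalized-state stream to a coordinates data.frame
#'
#' @param states list of [gen_state()].
#' @param model the `msk_model` (for coordinate names).
#' @return data.frame `time` + one column per coordinate.
#' @export
states_to_df <- function(states, model) {
  q <- t(vapply(states, function(s) s$q, numeric(n_coords(model))))
  df <- data.frame(time = vapply(states, function(s) s$t, numeric(1)))
  df[coord_names(model)] <- q
  df
}
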