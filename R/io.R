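# On-disk formats
#
# Both stream types are plain TSV with a small KEY<TAB>value header block
# followed by one row per sample/frame. Numeric cells are written with %.9g;
# marker gaps are empty cells. An optional trailing `sync` column (declared
# by a `SYNC 1` header line) carries the shared synchronization square wave
# sampled on that stream's own time base.

fmt_num <- function(x) {
  out <- sprintf("%.9g", x)
  out[is.na(x)] <- ""
  out
}

read_header_block <- function(lines, stop_keys) {
  hdr <- list()
  i <- 1L
  while (i <= length(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    key <- parts[[1]]
    if (key %in% stop_keys) {
      hdr[[key]] <- parts[-1]
      return(list(header = hdr, data_from = i + 1L))
    }
    if (!grepl("^[A-Z_]+$", key)) {
      stop_format(sprintf("line %d: expected a header line, got %s",
                          i, substr(lines[[i]], 1, 40)))
    }
    hdr[[key]] <- parts[-1]
    i <- i + 1L
  }
  stop_format(sprintf("missing header line: %s",
                      paste(stop_keys, collapse = " or ")))
}

parse_body <- function(lines, from, n_cols, what, allow_gaps = FALSE) {
  body <- lines[seq(from, length(lines))]
  body <- body[nzchar(body)]
  if (!length(body)) {
    stop_format(sprintf("%s file has no data rows", what))
  }
  cells <- strsplit(body, "\t", fixed = TRUE)
  nc <- lengths(cells)
  # a trailing empty cell is dropped by strsplit; pad
  cells[nc == n_cols - 1L] <- lapply(cells[nc == n_cols - 1L], c, "")
  nc <- lengths(cells)
  bad <- which(nc != n_cols)
  if (length(bad)) {
    stop_format(sprintf(
      "line %d: expected %d columns, found %d",
      from + bad[1] - 1L, n_cols, nc[bad[1]]))
  }
  flat <- unlist(cells, use.names = FALSE)
  vals <- suppressWarnings(as.numeric(flat))
  bad_cell <- which(is.na(vals) & nzchar(flat))
  if (length(bad_cell)) {
    row <- ceiling(bad_cell[1] / n_cols)
    stop_format(sprintf("line %d: non-numeric cell '%s'",
                        from + row - 1L, flat[bad_cell[1]]))
  }
  if (!allow_gaps && anyNA(vals)) {
    row <- ceiling(which(is.na(vals))[1] / n_cols)
    stop_format(sprintf("line %d: empty cell in a stream without gaps",
                        from + row - 1L))
  }
  matrix(vals, ncol = n_cols, byrow = TRUE)
}

header_rate <- function(hdr) {
  if (is.null(hdr$RATE_HZ)) stop_format("missing RATE_HZ header line")
  rate <- suppressWarnings(as.numeric(hdr$RATE_HZ[1]))
  if (is.na(rate) || rate <= 0) stop_format("RATE_HZ must be positive")
  rate
}

header_scalar <- function(hdr, key, default) {
  if (is.null(hdr[[key]])) default else hdr[[key]][1]
}

#' Read a multichannel EMG TSV file
#'
#' The file format is a key-value header block (`RATE_HZ`, optional `SIDE`,
#' `RUN`, `POSITION`, `SYNC`) terminated by a `CHANNELS` line naming the
#' channel columns, followed by one tab-separated sample row per time step.
#' When the header declares `SYNC 1`, the last data column is the
#' synchronization channel and is returned as the recording's `sync`
#' attribute rather than as an EMG channel.
#'
#' @param path path to the TSV file.
#' @param n_channels required number of EMG channels (default 7, the
#'   per-forearm electrode count).
#' @return an [emg_recording()].
#' @export
read_emg_tsv <- function(path, n_channels = 7) {
  lines <- readLines(path)
  h <- read_header_block(lines, "CHANNELS")
  hdr <- h$header
  chans <- hdr$CHANNELS
  has_sync <- identical(header_scalar(hdr, "SYNC", "0"), "1")
  if (length(chans) != n_channels) {
    stop_format(sprintf(
      "expected %d channels, CHANNELS line declares %d",
      n_channels, length(chans)))
  }
  n_cols <- length(chans) + has_sync
  m <- parse_body(lines, h$data_from, n_cols, "EMG")
  sync <- if (has_sync) m[, n_cols] else NULL
  samples <- m[, seq_along(chans), drop = FALSE]
  colnames(samples) <- chans
  run <- suppressWarnings(as.integer(header_scalar(hdr, "RUN", NA)))
  emg_recording(samples, header_rate(hdr),
                side = header_scalar(hdr, "SIDE", NA_character_),
                run = run,
                position = header_scalar(hdr, "POSITION", NA_character_),
                sync = sync)
}

#' Write a multichannel EMG TSV file
#'
#' Inverse of [read_emg_tsv()]: `read_emg_tsv(write_emg_tsv(x, p))`
#' reproduces `x`'s numeric content to the written precision, and writing
#' a just-read file reproduces it byte for byte.
#'
#' @param emg an [emg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_emg_tsv <- function(emg, path) {
  stopifnot(is_emg_recording(emg))
  sync <- attr(emg, "sync")
  hdr <- c(
    paste0("RATE_HZ\t", fmt_num(rate_hz(emg))),
    if (!is.na(attr(emg, "side"))) paste0("SIDE\t", attr(emg, "side")),
    if (!is.na(attr(emg, "run"))) paste0("RUN\t", attr(emg, "run")),
    if (!is.na(attr(emg, "position")))
      paste0("POSITION\t", attr(emg, "position")),
    if (!is.null(sync)) "SYNC\t1",
    paste0("CHANNELS\t", paste(names(emg), collapse = "\t")))
  m <- as.matrix(as.data.frame(emg))
  if (!is.null(sync)) m <- cbind(m, as.numeric(sync))
  body <- apply(matrix(fmt_num(m), nrow = nrow(m)), 1, paste,
                collapse = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a marker-trajectory TSV file
#'
#' Header block: `RATE_HZ`, optional `SIDE`/`RUN`/`POSITION`/`SYNC`, then a
#' `MARKERS` line naming the markers (three `x,y,z` columns each, in the
#' listed order). Empty cells mark gaps and become `NA`; the gap mask of the
#' returned object is `TRUE` exactly where cells were empty.
#'
#' @param path path to the TSV file.
#' @return a [marker_set()] (with a `sync` attribute when present).
#' @export
read_markers_tsv <- function(path) {
  lines <- readLines(path)
  h <- read_header_block(lines, "MARKERS")
  hdr <- h$header
  mks <- hdr$MARKERS
  missing <- setdiff(MARKER_NAMES, mks)
  extra <- setdiff(mks, MARKER_NAMES)
  if (length(missing) || length(extra)) {
    stop_format(paste0(
      "marker set must be exactly {", paste(MARKER_NAMES, collapse = ", "),
      "}",
      if (length(missing)) paste0("; missing: ",
                                  paste(missing, collapse = ", ")),
      if (length(extra)) paste0("; extra: ",
                                paste(extra, collapse = ", "))))
  }
  has_sync <- identical(header_scalar(hdr, "SYNC", "0"), "1")
  n_cols <- 3L * length(mks) + has_sync
  m <- parse_body(lines, h$data_from, n_cols, "marker", allow_gaps = TRUE)
  sync <- if (has_sync) m[, n_cols] else NULL
  coords <- m[, seq_len(3L * length(mks)), drop = FALSE]
  colnames(coords) <- as.vector(t(outer(mks, c("x", "y", "z"),
                                        paste, sep = "_")))
  rate <- header_rate(hdr)
  out <- marker_set(coords[, marker_cols(), drop = FALSE], rate,
                    side = header_scalar(hdr, "SIDE", NA_character_))
  if (has_sync) {
    if (anyNA(sync)) stop_format("sync column may not contain gaps")
    attr(out, "sync") <- sync_trace(sync, rate)
  }
  attr(out, "run") <- suppressWarnings(
    as.integer(header_scalar(hdr, "RUN", NA)))
  attr(out, "position") <- header_scalar(hdr, "POSITION", NA_character_)
  out
}

#' Write a marker-trajectory TSV file
#'
#' Inverse of [read_markers_tsv()]; gaps (`NA`) are written as empty cells.
#'
#' @param markers a [marker_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_markers_tsv <- function(markers, path) {
  stopifnot(is_marker_set(markers))
  sync <- attr(markers, "sync")
  hdr <- c(
    paste0("RATE_HZ\t", fmt_num(rate_hz(markers))),
    if (!is.na(attr(markers, "side"))) paste0("SIDE\t",
                                              attr(markers, "side")),
    if (!is.null(attr(markers, "run")) && !is.na(attr(markers, "run")))
      paste0("RUN\t", attr(markers, "run")),
    if (!is.null(attr(markers, "position")) &&
        !is.na(attr(markers, "position")))
      paste0("POSITION\t", attr(markers, "position")),
    if (!is.null(sync)) "SYNC\t1",
    paste0("MARKERS\t", paste(MARKER_NAMES, collapse = "\t")))
  m <- as.matrix(as.data.frame(markers))
  if (!is.null(sync)) m <- cbind(m, as.numeric(sync))
  body <- apply(matrix(fmt_num(m), nrow = nrow(m)), 1, paste,
                collapse = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Session manifest
#'
#' The manifest ties a recording session together: one row per
#' (run, position, side) combination naming that stream pair's EMG and
#' marker files. A complete session has 3 arm positions x 7 runs x 2 sides
#' = 42 rows.
#'
#' @param subject_id opaque subject label.
#' @param group `"able_bodied"` or `"amputee"`.
#' @param runs a data frame with columns `run`, `position`, `side`,
#'   `duration_s`, `active_dofs` (string such as `"1+2"`), `emg_file`,
#'   `marker_file`.
#' @return a `session_manifest` object.
#' @export
session_manifest <- function(subject_id, group, runs) {
  group <- match.arg(group, c("able_bodied", "amputee"))
  runs <- as_tibble(as.data.frame(runs))
  need <- c("run", "position", "side", "duration_s", "active_dofs",
            "emg_file", "marker_file")
  if (!all(need %in% names(runs))) {
    stop_format(paste("manifest runs table must have columns:",
                      paste(setdiff(need, names(runs)), collapse = ", ")))
  }
  structure(list(subject_id = subject_id, group = group,
                 runs = runs[need]),
            class = "session_manifest")
}

#' @export
print.session_manifest <- function(x, ...) {
  cat(sprintf("<session_manifest> subject=%s group=%s, %d stream pairs\n",
              x$subject_id, x$group, nrow(x$runs)))
  invisible(x)
}

#' Read a session manifest
#'
#' @param path path to a manifest TSV (key-value preamble with `SUBJECT`
#'   and `GROUP`, then a header row and one row per stream pair).
#' @return a [session_manifest()].
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  h <- read_header_block(lines, "RUN")
  hdr <- h$header
  cols <- c("RUN", "POSITION", "SIDE", "DURATION_S", "ACTIVE_DOFS",
            "EMG_FILE", "MARKER_FILE")
  got <- c("RUN", hdr$RUN)
  if (!identical(got, cols)) {
    stop_format(paste("manifest table header must be:",
                      paste(cols, collapse = " ")))
  }
  body <- lines[seq(h$data_from, length(lines))]
  body <- body[nzchar(body)]
  if (!length(body)) stop_format("manifest has no run rows")
  cells <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(cells) != length(cols))) {
    stop_format("manifest run rows must have 7 columns")
  }
  m <- do.call(rbind, cells)
  runs <- tibble(
    run = as.integer(m[, 1]), position = m[, 2], side = m[, 3],
    duration_s = as.numeric(m[, 4]), active_dofs = m[, 5],
    emg_file = m[, 6], marker_file = m[, 7])
  session_manifest(header_scalar(hdr, "SUBJECT", "unknown"),
                   header_scalar(hdr, "GROUP", "able_bodied"), runs)
}

#' Write a session manifest
#'
#' @param manifest a [session_manifest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "session_manifest"))
  r <- manifest$runs
  hdr <- c(paste0("SUBJECT\t", manifest$subject_id),
           paste0("GROUP\t", manifest$group),
           paste("RUN", "POSITION", "SIDE", "DURATION_S", "ACTIVE_DOFS",
                 "EMG_FILE", "MARKER_FILE", sep = "\t"))
  body <- sprintf("%d\t%s\t%s\t%s\t%s\t%s\t%s",
                  r$run, r$position, r$side, fmt_num(r$duration_s),
                  r$active_dofs, r$emg_file, r$marker_file)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Validate a session manifest
#'
#' Checks the session invariants: every (run 1..7, position, side)
#' combination present exactly once, positive durations, and active-DoF
#' labels matching the run protocol (runs 1-6 articulate two DoFs, run 7
#' all three). Missing combinations raise a completeness warning listing
#' them; an empty or duplicated table is an error.
#'
#' @param manifest a [session_manifest()].
#' @param dir optional directory against which to check that the named
#'   files exist.
#' @return `TRUE` invisibly if the manifest is complete.
#' @export
validate_manifest <- function(manifest, dir = NULL) {
  stopifnot(inherits(manifest, "session_manifest"))
  r <- manifest$runs
  if (!nrow(r)) stop_format("manifest is empty")
  key <- paste(r$run, r$position, r$side)
  if (anyDuplicated(key)) {
    stop_format(paste("duplicated manifest entries:",
                      paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  if (any(r$duration_s <= 0)) stop_format("durations must be positive")
  expected <- run_table()$active_dofs_label[match(r$run, run_table()$run)]
  bad <- which(is.na(expected) | r$active_dofs != expected)
  if (length(bad)) {
    stop_format(sprintf(
      "run %d at %s (%s): active_dofs '%s' does not match the protocol",
      r$run[bad[1]], r$position[bad[1]], r$side[bad[1]],
      r$active_dofs[bad[1]]))
  }
  grid <- expand.grid(run = 1:7, position = POSITIONS,
                      side = c("left", "right"),
                      stringsAsFactors = FALSE)
  want <- paste(grid$run, grid$position, grid$side)
  missing <- setdiff(want, key)
  if (length(missing)) {
    warn(c("incomplete session manifest",
           paste("missing (run position side):",
                 paste(missing, collapse = "; "))),
         class = "wristemg_completeness_warning")
    return(invisible(FALSE))
  }
  if (!is.null(dir)) {
    files <- c(file.path(dir, r$emg_file), file.path(dir, r$marker_file))
    absent <- files[!file.exists(files)]
    if (length(absent)) {
      stop_data(paste("manifest names missing files:",
                      paste(basename(absent), collapse = ", ")))
    }
  }
  invisible(TRUE)
}
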