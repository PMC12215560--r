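#' Write voltage trials as delimited text
#'
#' One `time` column plus one column per trial; trial metadata
#' (sampling rate, stimulus times, pulse width, holding potentials) go in
#' `#`-prefixed header lines so a single file round-trips a whole session.
#'
#' @param trials list of [voltage_trial()] with a common sampling rate and
#'   stimulus protocol.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_voltage_trials <- function(trials, path) {
  stopifnot(length(trials) >= 1)
  fs <- trials[[1]]$sampling_rate
  n <- length(trials[[1]]$samples)
  stopifnot(all(vapply(trials, function(tr) tr$sampling_rate == fs, TRUE)),
            all(vapply(trials, function(tr) length(tr$samples) == n, TRUE)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sampling_rate_hz=%.10g", fs),
    sprintf("# stim_times_s=%s",
            paste(trials[[1]]$stim_times, collapse = ",")),
    sprintf("# stim_duration_s=%.10g", trials[[1]]$stim_duration),
    sprintf("# holding_potentials_mv=%s",
            paste(vapply(trials, function(tr) tr$holding_potential, 0),
                  collapse = ","))
  ), con)
  m <- cbind(time = (seq_len(n) - 1) / fs,
             vapply(trials, function(tr) tr$samples, numeric(n)))
  colnames(m) <- c("time", paste0("trial_", seq_along(trials)))
  write.table(m, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read voltage trials written by [write_voltage_trials()]
#'
#' @param path file path.
#' @return list of [voltage_trial()].
#' @export
read_voltage_trials <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "# ")]
  get_meta <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, "="))]
    if (length(ln) != 1) stop("missing metadata line: ", key)
    sub(paste0("# ", key, "="), "", ln, fixed = TRUE)
  }
  fs <- as.numeric(get_meta("sampling_rate_hz"))
  stim <- as.numeric(strsplit(get_meta("stim_times_s"), ",")[[1]])
  stim <- stim[!is.na(stim)]
  stim_dur <- as.numeric(get_meta("stim_duration_s"))
  hold_raw <- strsplit(get_meta("holding_potentials_mv"), ",")[[1]]
  hold <- ifelse(hold_raw == "NA", NA_real_, suppressWarnings(as.numeric(hold_raw)))
  d <- read.table(path, header = TRUE, comment.char = "#", sep = "\t")
  lapply(seq_len(ncol(d) - 1L), function(i) {
    voltage_trial(d[[i + 1L]], fs, stim, stim_dur,
                  holding_potential = hold[i], id = i)
  })
}

#' Write/read per-ROI fluorescence traces as delimited text
#'
#' Columns `fg_cell`, `fr_cell`, `fg_neuropil`, `fr_neuropil`; frame rate,
#' plane depth and neuron id in `#` header lines.
#'
#' @param rec a [roi_recording()].
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_roi_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# frame_rate_hz=%.10g", rec$frame_rate),
    sprintf("# depth_um=%.10g", rec$depth),
    sprintf("# neuron_id=%s", rec$id)
  ), con)
  write.table(
    data.frame(fg_cell = rec$fg_cell, fr_cell = rec$fr_cell,
               fg_neuropil = rec$fg_neuropil, fr_neuropil = rec$fr_neuropil),
    con, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_roi_recording
#' @export
read_roi_recording <- function(path) {
  hdr <- readLines(path, n = 5)
  meta <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, "="))]
    sub(paste0("# ", key, "="), "", ln[1], fixed = TRUE)
  }
  d <- read.table(path, header = TRUE, comment.char = "#", sep = "\t")
  roi_recording(d$fg_cell, d$fr_cell, d$fg_neuropil, d$fr_neuropil,
                frame_rate = as.numeric(meta("frame_rate_hz")),
                depth = as.numeric(meta("depth_um")),
                id = meta("neuron_id"))
}

#' Read tracked snout coordinates
#'
#' Three-column delimited text: frame index, x, y (pixels).
#'
#' @param path file path.
#' @return data frame with columns `frame`, `x`, `y`.
#' @export
read_movement_xy <- function(path) {
  d <- read.table(path, header = TRUE, comment.char = "#")
  stopifnot(ncol(d) >= 3)
  names(d)[1:3] <- c("frame", "x", "y")
  d[, 1:3]
}
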