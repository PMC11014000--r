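# Reading, resampling and segmenting labelled tri-axial recordings.

#' Construct a labelled tri-axial sensor recording
#'
#' @param samples Numeric matrix, `n_samples x 3` (axes x, y, z).
#' @param labels Activity label per sample (length `n_samples`).
#' @param sampling_rate Sampling rate in Hz.
#' @param units `"g"` or `"m_per_s2"`.
#' @param subject_id,placement Provenance identifiers.
#' @return Object of class `"sensor_recording"`.
#' @export
sensor_recording <- function(samples, labels, sampling_rate,
                             units = c("m_per_s2", "g"),
                             subject_id = NA_character_,
                             placement = NA_character_) {
  units <- match.arg(units)
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) stop("`samples` must have three axis columns")
  if (any(!is.finite(samples))) stop("`samples` must be finite")
  if (length(labels) != nrow(samples)) {
    stop("`labels` must have one entry per sample")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be positive")
  }
  colnames(samples) <- c("x", "y", "z")
  structure(
    list(
      subject_id = as.character(subject_id),
      placement = as.character(placement),
      sampling_rate = as.numeric(sampling_rate),
      units = units,
      samples = samples,
      labels = as.character(labels)
    ),
    class = "sensor_recording"
  )
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf(
    "<sensor_recording> subject %s (%s): %d samples @ %g Hz [%s], %d activit%s\n",
    x$subject_id, x$placement, nrow(x$samples), x$sampling_rate, x$units,
    length(unique(x$labels)), if (length(unique(x$labels)) == 1L) "y" else "ies"
  ))
  invisible(x)
}

#' Construct a fixed-window segment
#'
#' @param samples Numeric matrix (`window_length x n_axes`).
#' @param label Single activity label.
#' @param subject_id,placement Provenance.
#' @return Object of class `"har_segment"`.
#' @export
har_segment <- function(samples, label, subject_id = NA_character_,
                        placement = NA_character_) {
  samples <- as.matrix(samples)
  structure(
    list(
      samples = samples,
      label = as.character(label)[1L],
      subject_id = as.character(subject_id),
      placement = as.character(placement),
      window_length = nrow(samples)
    ),
    class = "har_segment"
  )
}

#' Column-layout schema for a delimited recording file
#'
#' Describes how to read one dataset's files: which columns hold the
#' timestamp, the three acceleration axes and the activity label, the
#' delimiter and header convention, the acceleration units and the native
#' sampling rate.
#'
#' @param x,y,z,label Column names (or 1-based indices) of the three axes
#'   and the activity label.
#' @param timestamp Optional timestamp column (unused for computation,
#'   tolerated in files).
#' @param delim Field delimiter.
#' @param header Does the file carry a header row?
#' @param units Acceleration units in the file.
#' @param sampling_rate Native sampling rate in Hz.
#' @param placement Sensor placement recorded with the data.
#' @return Object of class `"recording_schema"`.
#' @seealso [dataset_schema()] for presets matching common public HAR
#'   dataset layouts.
#' @export
recording_schema <- function(x = "x", y = "y", z = "z", label = "label",
                             timestamp = NULL, delim = ",", header = TRUE,
                             units = c("m_per_s2", "g"), sampling_rate = 50,
                             placement = NA_character_) {
  units <- match.arg(units)
  structure(
    list(x = x, y = y, z = z, label = label, timestamp = timestamp,
         delim = delim, header = header, units = units,
         sampling_rate = as.numeric(sampling_rate),
         placement = as.character(placement)),
    class = "recording_schema"
  )
}

# Plausible default layouts for well-known public HAR datasets.  These are
# conveniences: rates and units reflect the published descriptions, column
# names may need adjusting to the exact export in hand.
.dataset_schemas <- function() {
  list(
    wisdm    = recording_schema(x = "x", y = "y", z = "z", label = "activity",
                                timestamp = "timestamp", units = "m_per_s2",
                                sampling_rate = 20, placement = "pocket"),
    harsense = recording_schema(x = "ax", y = "ay", z = "az", label = "activity",
                                units = "m_per_s2", sampling_rate = 50,
                                placement = "pocket"),
    harth    = recording_schema(x = "back_x", y = "back_y", z = "back_z",
                                label = "label", timestamp = "timestamp",
                                units = "g", sampling_rate = 50,
                                placement = "back"),
    har70plus = recording_schema(x = "back_x", y = "back_y", z = "back_z",
                                 label = "label", timestamp = "timestamp",
                                 units = "g", sampling_rate = 50,
                                 placement = "back"),
    mhealth  = recording_schema(x = "acc_chest_x", y = "acc_chest_y",
                                z = "acc_chest_z", label = "label",
                                delim = "\t", header = FALSE,
                                units = "m_per_s2", sampling_rate = 50,
                                placement = "chest"),
    pamap2   = recording_schema(x = "hand_acc_x", y = "hand_acc_y",
                                z = "hand_acc_z", label = "activity_id",
                                delim = " ", units = "m_per_s2",
                                sampling_rate = 100, placement = "hand"),
    realdisp = recording_schema(x = "acc_x", y = "acc_y", z = "acc_z",
                                label = "label", delim = "\t",
                                units = "m_per_s2", sampling_rate = 50,
                                placement = "wrist"),
    daliac   = recording_schema(x = "acc_x", y = "acc_y", z = "acc_z",
                                label = "label", units = "g",
                                sampling_rate = 204.8, placement = "wrist")
  )
}

#' Preset schemas for common public HAR datasets
#'
#' @param name One of `"wisdm"`, `"harsense"`, `"harth"`, `"har70plus"`,
#'   `"mhealth"`, `"pamap2"`, `"realdisp"`, `"daliac"`.
#' @return A `"recording_schema"`.
#' @export
dataset_schema <- function(name) {
  schemas <- .dataset_schemas()
  if (!name %in% names(schemas)) {
    stop(sprintf("unknown dataset schema '%s'; available: %s",
                 name, paste(names(schemas), collapse = ", ")))
  }
  schemas[[name]]
}

.pick_column <- function(df, col, what) {
  if (is.numeric(col)) {
    if (col > ncol(df)) stop(sprintf("schema column %d (%s) not in file", col, what))
    return(df[[col]])
  }
  if (!col %in% names(df)) {
    stop(sprintf("schema column '%s' (%s) not found in file", col, what))
  }
  df[[col]]
}

#' Read a labelled tri-axial recording from a delimited file
#'
#' Reads a CSV/TSV file according to a column schema and returns a
#' validated [sensor_recording()].  Rows whose acceleration values fail to
#' parse as finite numbers, or whose label is missing, are dropped with a
#' warning reporting the count.
#'
#' @param path File path.
#' @param schema A `"recording_schema"` (see [recording_schema()],
#'   [dataset_schema()]).
#' @param subject_id Subject identifier to attach.
#' @return A `"sensor_recording"`.
#' @export
read_recording <- function(path, schema, subject_id = NA_character_) {
  if (!inherits(schema, "recording_schema")) {
    stop("`schema` must be a recording_schema")
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, sep = schema$delim, header = schema$header,
                          stringsAsFactors = FALSE, comment.char = "",
                          fill = TRUE)
  if (nrow(df) == 0L) stop(sprintf("empty recording file: %s", path))

  ax <- suppressWarnings(as.numeric(.pick_column(df, schema$x, "x")))
  ay <- suppressWarnings(as.numeric(.pick_column(df, schema$y, "y")))
  az <- suppressWarnings(as.numeric(.pick_column(df, schema$z, "z")))
  lab <- as.character(.pick_column(df, schema$label, "label"))

  ok <- is.finite(ax) & is.finite(ay) & is.finite(az) &
    !is.na(lab) & nzchar(lab)
  if (!any(ok)) stop(sprintf("no parseable rows in %s", path))
  if (any(!ok)) {
    warning(sprintf("dropped %d unparseable row(s) from %s", sum(!ok), path))
  }

  sensor_recording(
    samples = cbind(ax[ok], ay[ok], az[ok]),
    labels = lab[ok],
    sampling_rate = schema$sampling_rate,
    units = schema$units,
    subject_id = subject_id,
    placement = schema$placement
  )
}

# Continued-fraction rational approximation p/q of a positive real.
.rational <- function(r, max_den = 10000L, tol = 1e-9) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  x <- r
  repeat {
    a <- floor(x)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(r - p1 / q1) < tol * r) break
    if (abs(x - a) < 1e-12) break
    x <- 1 / (x - a)
  }
  c(p = as.integer(p1), q = as.integer(q1))
}

#' Resample a recording to a target rate
#'
#' Rational-ratio polyphase resampling (via [signal::resample()]) of each
#' axis, with the built-in anti-aliasing low-pass when decimating.  Labels
#' are carried over from the nearest original sample.  Resampling to the
#' recording's own rate is the identity.  Upsampling (target above the
#' native rate) is supported by the same machinery and flagged with a
#' warning, since it adds no information.
#'
#' @param recording A `"sensor_recording"`.
#' @param target_rate Target rate in Hz (default 50, the common rate the
#'   analysis pipeline standardizes on).
#' @return A `"sensor_recording"` at `target_rate`.
#' @export
resample_recording <- function(recording, target_rate = 50) {
  if (!inherits(recording, "sensor_recording")) {
    stop("`recording` must be a sensor_recording")
  }
  if (!is.numeric(target_rate) || target_rate <= 0) {
    stop("`target_rate` must be positive")
  }
  if (isTRUE(all.equal(target_rate, recording$sampling_rate))) {
    return(recording)
  }
  if (target_rate > recording$sampling_rate) {
    warning(sprintf(
      "upsampling from %g Hz to %g Hz adds no information",
      recording$sampling_rate, target_rate
    ))
  }
  pq <- .rational(target_rate / recording$sampling_rate)
  new_samples <- apply(recording$samples, 2L, function(col) {
    as.numeric(signal::resample(col, pq["p"], pq["q"]))
  })
  n_new <- nrow(new_samples)
  # label of the nearest original sample
  orig_idx <- round((seq_len(n_new) - 1L) * recording$sampling_rate / target_rate) + 1L
  orig_idx <- pmin(pmax(orig_idx, 1L), length(recording$labels))
  sensor_recording(
    samples = new_samples,
    labels = recording$labels[orig_idx],
    sampling_rate = target_rate,
    units = recording$units,
    subject_id = recording$subject_id,
    placement = recording$placement
  )
}

#' Convert a recording between g and m/s^2
#'
#' Explicit unit conversion (factor 9.80665 m/s^2 per g).  Conversion is
#' never performed silently elsewhere in the package: the
#' energy-to-entropy ratio scales with squared signal amplitude, so mixing
#' units across recordings distorts comparisons.
#'
#' @param recording A `"sensor_recording"`.
#' @param to Target units.
#' @return The converted recording (identity if already in `to`).
#' @export
convert_units <- function(recording, to = c("m_per_s2", "g")) {
  to <- match.arg(to)
  if (recording$units == to) return(recording)
  factor <- if (to == "m_per_s2") 9.80665 else 1 / 9.80665
  recording$samples <- recording$samples * factor
  recording$units <- to
  recording
}

#' Cut a recording into fixed-duration labelled windows
#'
#' Slices the recording into consecutive windows of
#' `round(window_seconds * sampling_rate)` samples.  Under the default
#' `"pure"` label policy a window is emitted only if all of its samples
#' share one activity label, and windows never straddle a label change;
#' trailing partial windows are dropped.  The `"majority"` policy emits
#' every full window and labels it by majority vote.
#'
#' @param recording A `"sensor_recording"`, already at the analysis rate.
#' @param window_seconds Window duration in seconds (default 2.5).
#' @param overlap Fractional overlap between consecutive windows in
#'   `[0, 1)`; default 0 (non-overlapping).
#' @param label_policy `"pure"` or `"majority"`.
#' @return List of `"har_segment"` objects (possibly empty).
#' @export
segment_recording <- function(recording, window_seconds = 2.5, overlap = 0,
                              label_policy = c("pure", "majority")) {
  if (!inherits(recording, "sensor_recording")) {
    stop("`recording` must be a sensor_recording")
  }
  label_policy <- match.arg(label_policy)
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)")
  wl <- as.integer(round(window_seconds * recording$sampling_rate))
  if (wl < 1L) stop("window shorter than one sample")
  step <- max(1L, as.integer(round(wl * (1 - overlap))))

  make_seg <- function(start, label) {
    har_segment(
      recording$samples[start:(start + wl - 1L), , drop = FALSE],
      label = label,
      subject_id = recording$subject_id,
      placement = recording$placement
    )
  }

  out <- list()
  if (label_policy == "pure") {
    runs <- rle(recording$labels)
    run_end <- cumsum(runs$lengths)
    run_start <- run_end - runs$lengths + 1L
    for (r in seq_along(runs$values)) {
      s <- run_start[r]
      while (s + wl - 1L <= run_end[r]) {
        out[[length(out) + 1L]] <- make_seg(s, runs$values[r])
        s <- s + step
      }
    }
  } else {
    s <- 1L
    n <- nrow(recording$samples)
    while (s + wl - 1L <= n) {
      labs <- recording$labels[s:(s + wl - 1L)]
      win <- names(sort(table(labs), decreasing = TRUE))[1L]
      out[[length(out) + 1L]] <- make_seg(s, win)
      s <- s + step
    }
  }
  out
}

#' Write segments to a directory of delimited files
#'
#' One CSV per segment (columns x, y, z) plus a `manifest.csv` listing
#' file, subject, placement, label and window length.
#'
#' @param segments List of `"har_segment"` objects.
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_segments <- function(segments, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(segments), function(i) {
    seg <- segments[[i]]
    fn <- sprintf("segment_%05d.csv", i)
    utils::write.csv(as.data.frame(seg$samples), file.path(dir, fn),
                     row.names = FALSE, quote = FALSE)
    data.frame(file = fn, subject_id = seg$subject_id,
               placement = seg$placement, label = seg$label,
               window_length = seg$window_length, stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE,
                   quote = FALSE)
  invisible(manifest)
}
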