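# Energy-to-Shannon-entropy fitness statistics for mother-wavelet selection.
#
# The statistic treats the terminal level of the packet decomposition as a
# single pooled coefficient set (the default; a per-node variant is
# available): energy is the summed squared coefficients, the energy
# probability distribution is each squared coefficient over the total, and
# the Shannon entropy of that distribution measures how spread out the
# energy is.  A wavelet whose shape matches the signal concentrates energy
# in few coefficients — high energy, low entropy, high ratio.

.degenerate_error <- function(msg) {
  stop(errorCondition(msg, class = c("mwselect_degenerate", "error", "condition")))
}

.pooled_coefficients <- function(packet) {
  if (!inherits(packet, "wpt_packet")) stop("`packet` must be a wpt_packet")
  unlist(packet$nodes, use.names = FALSE)
}

#' Packet energy at the terminal level
#'
#' Sum of squared coefficients pooled over all terminal nodes of the
#' decomposition.  For orthogonal wavelets this equals the energy of the
#' (padded) input signal.
#'
#' @param packet A `"wpt_packet"` from [wpt_decompose()].
#' @return Non-negative scalar, in squared signal units.
#' @export
level_energy <- function(packet) {
  sum(.pooled_coefficients(packet)^2)
}

#' Energy probability distribution of packet coefficients
#'
#' Each coefficient's squared value as a fraction of the total level
#' energy.  The result is a probability vector: all entries in `[0, 1]`,
#' summing to one, and invariant under rescaling of the input signal.
#'
#' @inheritParams level_energy
#' @return Numeric vector of length `padded_length` summing to 1.
#' @export
energy_probabilities <- function(packet) {
  coefs <- .pooled_coefficients(packet)
  e <- sum(coefs^2)
  if (e <= 0) .degenerate_error("degenerate segment: zero-energy packet")
  coefs^2 / e
}

#' Shannon entropy of the coefficient energy distribution
#'
#' \eqn{-\sum_i P_i \log P_i} over the energy probabilities, with the
#' convention \eqn{0 \log 0 = 0}.  Bounded between 0 (all energy in one
#' coefficient) and \eqn{\log m} (energy spread uniformly over all `m`
#' coefficients).
#'
#' @inheritParams level_energy
#' @param base Base of the logarithm; natural log (nats) by default.
#'   Rankings built on the energy-to-entropy ratio do not depend on the
#'   base, which rescales every entropy by the same constant.
#' @return Entropy in `[0, log(m)]`.
#' @export
shannon_entropy <- function(packet, base = exp(1)) {
  p <- energy_probabilities(packet)
  nz <- p > 0
  max(0, -sum(p[nz] * log(p[nz], base = base)))
}

#' Energy-to-Shannon-entropy ratio
#'
#' The fitness statistic for mother-wavelet selection: level energy
#' divided by the Shannon entropy of the energy distribution.  High values
#' indicate that the wavelet represents the signal with few large
#' coefficients.  Note the ratio carries squared signal units — scaling
#' the signal by `a` scales the ratio by `a^2` — so ratios are only
#' comparable across recordings measured in the same units.
#'
#' @inheritParams shannon_entropy
#' @return Non-negative scalar (signal units squared per log unit).
#' @export
energy_entropy_ratio <- function(packet, base = exp(1)) {
  e <- level_energy(packet)
  s <- shannon_entropy(packet, base = base)
  if (s <= 0) {
    .degenerate_error(
      "undefined ratio: zero entropy (all energy in a single coefficient)"
    )
  }
  e / s
}

# Per-axis ratio/energy/entropy for one segment; respects the pooling mode.
# Returns list(energy, entropy, ratio) each a vector over axes, or signals
# a degenerate condition.
.segment_fitness <- function(samples, w, level, base, pooling) {
  apply_one <- function(col) {
    pk <- wpt_decompose(col, w, level)
    if (pooling == "pooled") {
      c(level_energy(pk), shannon_entropy(pk, base), energy_entropy_ratio(pk, base))
    } else {
      per <- vapply(seq_along(pk$nodes), function(i) {
        sub <- pk
        sub$nodes <- pk$nodes[i]
        c(level_energy(sub), shannon_entropy(sub, base), energy_entropy_ratio(sub, base))
      }, numeric(3))
      rowMeans(per)
    }
  }
  vals <- apply(samples, 2L, apply_one)
  list(energy = vals[1L, ], entropy = vals[2L, ], ratio = vals[3L, ])
}

.segment_matrix <- function(segment, axis_mode) {
  m <- if (inherits(segment, "har_segment")) segment$samples else as.matrix(segment)
  if (axis_mode == "magnitude") {
    m <- matrix(sqrt(rowSums(m^2)), ncol = 1L)
  }
  m
}

.segment_label <- function(segment) {
  if (inherits(segment, "har_segment")) as.character(segment$label) else "all"
}

#' Score one mother wavelet on a set of segments
#'
#' Decomposes every segment with the given wavelet, computes the
#' energy-to-entropy ratio per axis, averages over axes, then over
#' segments.  Segments with zero energy or zero entropy (for which the
#' ratio is undefined) are excluded from the averages and counted.
#'
#' @param segments A list of segments (`"har_segment"` objects or plain
#'   numeric matrices, one column per axis).
#' @param wavelet Wavelet name or `"wavelet_spec"`.
#' @param level Decomposition level (default 3).
#' @param base Entropy logarithm base (default natural log).
#' @param pooling `"pooled"` (all terminal coefficients as one set, the
#'   default) or `"per_node"` (statistic per node, averaged over nodes).
#' @param axis_mode `"mean"` (ratio per axis, averaged; the default) or
#'   `"magnitude"` (single ratio of the Euclidean norm signal).
#' @return Object of class `"fitness_result"`: list with `wavelet_name`,
#'   `activity`, `axis`, `mean_energy`, `mean_entropy`, `mean_ratio`,
#'   `n_segments` (used) and `n_degenerate` (excluded).
#' @export
score_wavelet <- function(segments, wavelet, level = 3L, base = exp(1),
                          pooling = c("pooled", "per_node"),
                          axis_mode = c("mean", "magnitude")) {
  pooling <- match.arg(pooling)
  axis_mode <- match.arg(axis_mode)
  if (length(segments) < 1L) stop("need at least one segment")
  w <- wavelet_filters(wavelet)

  per_seg <- lapply(segments, function(seg) {
    m <- .segment_matrix(seg, axis_mode)
    tryCatch(
      {
        f <- .segment_fitness(m, w, level, base, pooling)
        c(mean(f$energy), mean(f$entropy), mean(f$ratio))
      },
      mwselect_degenerate = function(cnd) NULL
    )
  })
  keep <- !vapply(per_seg, is.null, logical(1))
  n_bad <- sum(!keep)
  if (!any(keep)) stop("all segments are degenerate (zero energy or zero entropy)")
  if (n_bad > 0L) {
    warning(sprintf("%d degenerate segment(s) excluded from aggregation", n_bad))
  }
  vals <- do.call(rbind, per_seg[keep])

  structure(
    list(
      wavelet_name = w$name,
      activity = "all",
      axis = if (axis_mode == "mean") "mean" else "magnitude",
      mean_energy = mean(vals[, 1L]),
      mean_entropy = mean(vals[, 2L]),
      mean_ratio = mean(vals[, 3L]),
      n_segments = sum(keep),
      n_degenerate = n_bad
    ),
    class = "fitness_result"
  )
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf(
    "<fitness_result> %s (%s axes, %d segments%s)\n  mean energy %.6g  mean entropy %.6g  mean ratio %.6g\n",
    x$wavelet_name, x$axis, x$n_segments,
    if (x$n_degenerate > 0) sprintf(", %d degenerate excluded", x$n_degenerate) else "",
    x$mean_energy, x$mean_entropy, x$mean_ratio
  ))
  invisible(x)
}

.rank_table <- function(df) {
  ord <- order(-df$mean_ratio, df$wavelet)  # ties broken by name
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Rank candidate mother wavelets on a labelled dataset
#'
#' Computes the mean energy-to-Shannon-entropy ratio of every candidate
#' wavelet over all segments (the overall table) and within each activity
#' (per-activity tables), and ranks candidates by descending mean ratio.
#' The overall rank-1 wavelet is the selected mother wavelet.  Ties are
#' broken lexicographically by wavelet name so reports are deterministic.
#'
#' @param segments A list of labelled `"har_segment"` objects.
#' @param candidates Character vector of candidate wavelet names; default
#'   the full registry ([candidate_wavelets()]).
#' @inheritParams score_wavelet
#' @return Object of class `"selection_report"`: list with `overall` and
#'   `per_activity` data frames (columns `wavelet`, `activity`,
#'   `mean_energy`, `mean_entropy`, `mean_ratio`, `n_segments`, `rank`)
#'   and `selected`, the winning wavelet name.
#' @export
select_mother_wavelet <- function(segments, candidates = candidate_wavelets(),
                                  level = 3L, base = exp(1),
                                  pooling = c("pooled", "per_node"),
                                  axis_mode = c("mean", "magnitude")) {
  pooling <- match.arg(pooling)
  axis_mode <- match.arg(axis_mode)
  if (length(candidates) < 1L) stop("empty candidate list")
  if (length(segments) < 1L) stop("need at least one labelled segment")

  labels <- vapply(segments, .segment_label, character(1))
  activities <- sort(unique(labels))

  score_rows <- function(segs, activity) {
    rows <- lapply(candidates, function(cand) {
      fr <- score_wavelet(segs, cand, level = level, base = base,
                          pooling = pooling, axis_mode = axis_mode)
      data.frame(
        wavelet = fr$wavelet_name, activity = activity,
        mean_energy = fr$mean_energy, mean_entropy = fr$mean_entropy,
        mean_ratio = fr$mean_ratio, n_segments = fr$n_segments,
        stringsAsFactors = FALSE
      )
    })
    .rank_table(do.call(rbind, rows))
  }

  overall <- score_rows(segments, "all")
  per_activity <- do.call(rbind, lapply(activities, function(a) {
    score_rows(segments[labels == a], a)
  }))
  rownames(per_activity) <- NULL

  structure(
    list(
      overall = overall,
      per_activity = per_activity,
      selected = overall$wavelet[overall$rank == 1L]
    ),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> selected mother wavelet: %s\n\n", x$selected))
  print(x$overall, ...)
  invisible(x)
}

#' Write a selection report as delimited text
#'
#' Writes the overall and per-activity ranking tables as one CSV
#' (columns: wavelet, activity, mean_energy, mean_entropy, mean_ratio,
#' n_segments, rank).
#'
#' @param report A `"selection_report"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path) {
  if (!inherits(report, "selection_report")) {
    stop("`report` must be a selection_report")
  }
  utils::write.csv(rbind(report$overall, report$per_activity), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
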