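# Window construction: turns a labeled clip into the three input forms the
# model variants consume. Windows are index views over the stored clip —
# frames are gathered only when a batch is materialized.

#' Binary frame-label track for one phase
#'
#' `labels[k+1] == 1` iff 0-based frame `k` lies in the phase's half-open
#' interval; reversed intervals (PDT/LVCRT with end before start) use their
#' `[min, max)` span.
#'
#' @param events a valid [event_set()].
#' @param phase one of [PHASE_NAMES].
#' @param clip_length number of frames; must exceed every event index.
#' @return integer vector of 0/1, length `clip_length`.
#' @export
label_frames <- function(events, phase, clip_length) {
  validate_event_set(events)
  if (clip_length <= max(unlist(events[EVENT_NAMES]))) {
    stop("clip_length ", clip_length, " inconsistent with events (max index ",
         max(unlist(events[EVENT_NAMES])), ")")
  }
  iv <- events_to_phase_interval(events, phase)
  k <- seq_len(clip_length) - 1L
  as.integer(k >= iv$start & k < iv$end)
}

new_window_set <- function(clip, form, labels, ...) {
  structure(c(list(clip = clip, form = form, labels = labels), list(...)),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %s: %d samples from clip %s\n",
              x$form, n_windows(x), x$clip$clip_id))
  invisible(x)
}

#' Number of window samples in a window set
#' @param ws a window set.
#' @export
n_windows <- function(ws) {
  if (ws$form == "segment") length(ws$starts) else length(ws$centers)
}

clip_T <- function(clip) dim(clip$frames)[1]

#' Center-labeled L-frame windows (DEFAULT variant input)
#'
#' Each sample is `L` consecutive frames labeled by the phase membership of
#' its center frame — for a 7-frame input the label is 1 iff the 4th frame is
#' in the phase. Under `edge_policy = "drop"` only fully interior centers are
#' kept (`T - L + 1` windows); under `"replicate"` every frame is a center and
#' out-of-range frames repeat the clip edges, so a prediction exists for every
#' frame.
#'
#' @param clip a `video_clip`.
#' @param track label track from [label_frames()] (length `T`).
#' @param L odd window length (7 or 13 in the source configuration).
#' @param edge_policy `"replicate"` (default) or `"drop"`.
#' @return a `window_set` of form `"center"`.
#' @export
make_center_windows <- function(clip, track, L,
                                edge_policy = c("replicate", "drop")) {
  edge_policy <- match.arg(edge_policy)
  check_window_args(clip, track, L)
  Tn <- clip_T(clip)
  half <- (L - 1L) %/% 2L
  centers <- if (edge_policy == "drop") {
    if (L > Tn) {
      warning("window length L = ", L, " exceeds clip length ", Tn,
              " under drop policy; no windows produced")
      integer(0)
    } else seq(half, Tn - 1L - half)
  } else seq(0L, Tn - 1L)
  new_window_set(clip, "center", labels = track[centers + 1L],
                 centers = centers, L = as.integer(L),
                 edge_policy = edge_policy)
}

#' Paired forward/backward windows (BIDIRECTIONAL variant input)
#'
#' For each center `c` the pair covers the `2L - 1` frames `[c-L+1, c+L-1]`:
#' the forward stream M1 sees the first `L` frames (ending at the center), the
#' backward stream M2 the last `L` (starting at the center); both share the
#' center frame, whose phase membership is the label.
#'
#' @inheritParams make_center_windows
#' @return a `window_set` of form `"bidirectional"`.
#' @export
make_bidirectional_pairs <- function(clip, track, L,
                                     edge_policy = c("replicate", "drop")) {
  edge_policy <- match.arg(edge_policy)
  check_window_args(clip, track, L)
  Tn <- clip_T(clip)
  span <- 2L * L - 1L
  centers <- if (edge_policy == "drop") {
    if (span > Tn) {
      warning("receptive field 2L-1 = ", span, " exceeds clip length ", Tn,
              " under drop policy; no windows produced")
      integer(0)
    } else seq(L - 1L, Tn - L)
  } else seq(0L, Tn - 1L)
  new_window_set(clip, "bidirectional", labels = track[centers + 1L],
                 centers = centers, L = as.integer(L),
                 edge_policy = edge_policy)
}

#' Per-frame-labeled segments (CONV-SA variant input)
#'
#' Tiles the clip into `W`-frame segments at the given stride (default `W`,
#' non-overlapping). The final partial segment is padded by replicating the
#' last frame; padded positions are masked out of the label vector.
#'
#' @param clip a `video_clip`.
#' @param track label track from [label_frames()].
#' @param W segment length (>= 1).
#' @param stride step between segment starts (default `W`).
#' @return a `window_set` of form `"segment"`; each sample carries a length-`W`
#'   label vector and a logical mask of real (non-padded) positions.
#' @export
make_segment_windows <- function(clip, track, W, stride = W) {
  stopifnot(W >= 1, stride >= 1)
  Tn <- clip_T(clip)
  if (length(track) != Tn) {
    stop("track length ", length(track), " != clip length ", Tn)
  }
  starts <- seq(0L, Tn - 1L, by = stride)
  starts <- starts[starts == 0L | starts < Tn]
  labels <- lapply(starts, function(s) {
    idx <- s + seq_len(W) - 1L
    track[pmin(idx, Tn - 1L) + 1L]
  })
  masks <- lapply(starts, function(s) (s + seq_len(W) - 1L) < Tn)
  new_window_set(clip, "segment", labels = labels, starts = as.integer(starts),
                 W = as.integer(W), stride = as.integer(stride), masks = masks)
}

check_window_args <- function(clip, track, L) {
  if (L %% 2L == 0L) stop("window length L must be odd so the center frame is unambiguous")
  if (length(track) != clip_T(clip)) {
    stop("track length ", length(track), " != clip length ", clip_T(clip))
  }
  invisible(TRUE)
}

# clamp 0-based frame indices to the clip (replicate edge policy)
clamp_frames <- function(idx, Tn) pmin(pmax(idx, 0L), Tn - 1L)

#' Materialize the frames of one window sample
#'
#' @param ws a `window_set`.
#' @param i sample index (1-based).
#' @return For form `"center"` an `L x H x W x C` array; `"bidirectional"` a
#'   list with `m1`, `m2` (each `L x H x W x C`); `"segment"` a list with
#'   `frames` (`W x H x W x C`) and `mask`.
#' @export
window_frames <- function(ws, i) {
  Tn <- clip_T(ws$clip)
  fr <- ws$clip$frames
  if (ws$form == "center") {
    c0 <- ws$centers[i]
    half <- (ws$L - 1L) %/% 2L
    idx <- clamp_frames(seq(c0 - half, c0 + half), Tn)
    fr[idx + 1L, , , , drop = FALSE]
  } else if (ws$form == "bidirectional") {
    c0 <- ws$centers[i]
    m1 <- clamp_frames(seq(c0 - ws$L + 1L, c0), Tn)
    m2 <- clamp_frames(seq(c0, c0 + ws$L - 1L), Tn)
    list(m1 = fr[m1 + 1L, , , , drop = FALSE],
         m2 = fr[m2 + 1L, , , , drop = FALSE])
  } else {
    s <- ws$starts[i]
    idx <- clamp_frames(s + seq_len(ws$W) - 1L, Tn)
    list(frames = fr[idx + 1L, , , , drop = FALSE], mask = ws$masks[[i]])
  }
}

#' Reconstruct a frame-label track from replicate-policy center windows
#'
#' Inverse of [make_center_windows()] under the replicate edge policy (and of
#' [make_bidirectional_pairs()] likewise): window `i`'s label is the track
#' value at its center, and replicate centers enumerate every frame once.
#' @param ws a `window_set` with one window per frame.
#' @export
track_from_windows <- function(ws) {
  if (ws$form == "segment") {
    Tn <- clip_T(ws$clip)
    out <- integer(Tn)
    for (i in seq_along(ws$starts)) {
      keep <- ws$masks[[i]]
      out[ws$starts[i] + which(keep)] <- ws$labels[[i]][keep]
    }
    return(out)
  }
  if (length(ws$centers) != clip_T(ws$clip)) {
    stop("track reconstruction needs one window per frame (replicate policy)")
  }
  ws$labels[order(ws$centers)]
}

#' Serialize a label track to CSV (`frame,label`)
#' @param track integer 0/1 vector.
#' @param path output path.
#' @export
write_label_track <- function(track, path) {
  write.csv(data.frame(frame = seq_along(track) - 1L, label = track),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_label_track
#' @export
read_label_track <- function(path) {
  df <- read.csv(path)
  df$label[order(df$frame)]
}
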