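#' @useDynLib swallowphase, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif qnorm pnorm uniroot sd predict coef
#' @importFrom utils read.csv write.csv head tail
NULL

#' Names of the seven swallowing events, in temporal-parameter order
#'
#' The canonical column order used by annotation files and [event_set()].
#' @export
EVENT_NAMES <- c(
  "oral_start", "bolus_past_mandible", "hyoid_burst",
  "lvc_onset", "ues_opening", "ues_closure", "lvc_offset"
)

#' Names of the seven temporal parameters / phases
#'
#' OPD: oral phase duration. PDT: pharyngeal delay time. PRT: pharyngeal
#' response time. PTT: pharyngeal transit time. LVCRT: laryngeal vestibule
#' closure reaction time. LVC_DURATION: laryngeal vestibule closure duration.
#' UESOD: upper esophageal sphincter opening duration.
#' @export
PHASE_NAMES <- c("OPD", "PDT", "PRT", "PTT", "LVCRT", "LVC_DURATION", "UESOD")

#' Construct a validated set of swallowing-event frame indices
#'
#' An `event_set` holds the seven labeled event frame indices for one clip:
#' the start of the oral phase (by convention frame 0, the first frame of the
#' first sub-swallow), the frame where the bolus leading edge passes the ramus
#' of the mandible, the first frame of the hyoid bone's anterosuperior burst,
#' laryngeal vestibule closure (LVC) onset and offset, and upper esophageal
#' sphincter (UES) opening and closure.
#'
#' Ordering constraints are deliberately minimal: the hyoid burst may precede
#' the bolus passing the mandible, and LVC onset may precede the hyoid burst —
#' both orders occur in clinical recordings, which is why the pharyngeal delay
#' time and LVC reaction time are signed quantities.
#'
#' @param clip_id character identifier for the clip.
#' @param oral_start frame index of oral phase start; must be 0.
#' @param bolus_past_mandible,hyoid_burst,lvc_onset,ues_opening,ues_closure,lvc_offset
#'   0-based integer frame indices of the remaining six events.
#' @param clip_length optional total number of frames; when supplied, all
#'   indices must be strictly below it.
#' @return an object of class `"event_set"` (a named list).
#' @examples
#' ev <- event_set("clip1", 0, 10, 13, 15, 16, 22, 24)
#' compute_parameters(ev, fps = 15)
#' @export
event_set <- function(clip_id, oral_start = 0L, bolus_past_mandible,
                      hyoid_burst, lvc_onset, ues_opening, ues_closure,
                      lvc_offset, clip_length = NULL) {
  ev <- structure(list(
    clip_id = as.character(clip_id),
    oral_start = as.integer(oral_start),
    bolus_past_mandible = as.integer(bolus_past_mandible),
    hyoid_burst = as.integer(hyoid_burst),
    lvc_onset = as.integer(lvc_onset),
    ues_opening = as.integer(ues_opening),
    ues_closure = as.integer(ues_closure),
    lvc_offset = as.integer(lvc_offset),
    clip_length = if (is.null(clip_length)) NULL else as.integer(clip_length)
  ), class = "event_set")
  validate_event_set(ev)
  ev
}

#' Validate an event_set against its invariants
#'
#' Checks: `oral_start == 0`; all indices are non-negative integers;
#' `oral_start <= bolus_past_mandible`; `ues_opening < ues_closure`;
#' `lvc_onset < lvc_offset`; all indices `< clip_length` when known. No
#' ordering is imposed between the hyoid burst and the bolus passing the
#' mandible, between LVC onset and the hyoid burst, or between LVC offset and
#' UES closure.
#'
#' @param events an `event_set`.
#' @return `events`, invisibly; errors name the violated constraint.
#' @export
validate_event_set <- function(events) {
  idx <- unlist(events[EVENT_NAMES])
  if (anyNA(idx)) {
    stop("event_set '", events$clip_id, "': missing or non-integer frame index")
  }
  if (any(idx < 0L)) {
    stop("event_set '", events$clip_id, "': negative frame index (all events must be >= 0)")
  }
  if (events$oral_start != 0L) {
    stop("event_set '", events$clip_id, "': oral_start must be 0 (first frame of the first sub-swallow)")
  }
  if (events$bolus_past_mandible < events$oral_start) {
    stop("event_set '", events$clip_id, "': bolus_past_mandible precedes oral_start")
  }
  if (events$ues_opening >= events$ues_closure) {
    stop("event_set '", events$clip_id, "': ues_opening must precede ues_closure")
  }
  if (events$lvc_onset >= events$lvc_offset) {
    stop("event_set '", events$clip_id, "': lvc_onset must precede lvc_offset")
  }
  if (!is.null(events$clip_length) && any(idx >= events$clip_length)) {
    stop("event_set '", events$clip_id, "': event index at or beyond clip_length")
  }
  invisible(events)
}

#' @export
print.event_set <- function(x, ...) {
  cat("<event_set>", x$clip_id, "\n")
  for (nm in EVENT_NAMES) cat(sprintf("  %-20s %d\n", nm, x[[nm]]))
  if (!is.null(x$clip_length)) cat(sprintf("  %-20s %d\n", "clip_length", x$clip_length))
  invisible(x)
}

#' Convert a signed frame count to a duration
#'
#' At the fluoroscopy frame rate (15 FPS in the source recordings) one frame
#' corresponds to 1000/fps milliseconds. The conversion is linear and
#' sign-preserving, so negative frame counts (a pharyngeal delay time where the
#' hyoid burst precedes the bolus passing the mandible) map to negative
#' durations.
#'
#' @param n_frames signed frame count (may be fractional, e.g. a mean).
#' @param fps frames per second; must be positive.
#' @param unit `"ms"` (default) or `"s"`.
#' @param rounded if `TRUE`, seconds are rounded half-to-even to 3 decimals,
#'   matching how phase-duration tables are conventionally presented;
#'   milliseconds are returned unrounded regardless.
#' @return the duration in the requested unit.
#' @examples
#' frames_to_duration(27.658, 15, "s", rounded = TRUE) # 1.844
#' frames_to_duration(15, 15, "s")                     # 1
#' @export
frames_to_duration <- function(n_frames, fps, unit = c("ms", "s"),
                               rounded = FALSE) {
  unit <- match.arg(unit)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("fps must be a single positive number")
  }
  out <- if (unit == "ms") n_frames * (1000 / fps) else n_frames / fps
  if (rounded && unit == "s") out <- round(out, 3) else out
}

#' Compute the seven temporal parameters from labeled events
#'
#' Each parameter is a difference of two event frame indices converted to
#' milliseconds:
#' \describe{
#'   \item{OPD}{bolus_past_mandible − oral_start}
#'   \item{PDT}{hyoid_burst − bolus_past_mandible (may be negative)}
#'   \item{PRT}{ues_closure − hyoid_burst}
#'   \item{PTT}{ues_closure − bolus_past_mandible (= PDT + PRT)}
#'   \item{LVCRT}{lvc_onset − hyoid_burst (may be negative)}
#'   \item{LVC_DURATION}{lvc_offset − lvc_onset}
#'   \item{UESOD}{ues_closure − ues_opening}
#' }
#'
#' @param events a valid [event_set()].
#' @param fps frames per second of the clip.
#' @return an object of class `"temporal_parameters"`: a named list with
#'   elements `opd_ms`, `pdt_ms`, `prt_ms`, `ptt_ms`, `lvcrt_ms`, `lvcd_ms`,
#'   `uesod_ms` and `fps`.
#' @export
compute_parameters <- function(events, fps) {
  validate_event_set(events)
  fr <- phase_frame_counts(events)
  out <- lapply(fr, frames_to_duration, fps = fps, unit = "ms")
  names(out) <- c("opd_ms", "pdt_ms", "prt_ms", "ptt_ms", "lvcrt_ms",
                  "lvcd_ms", "uesod_ms")
  out$fps <- fps
  out$clip_id <- events$clip_id
  structure(out, class = "temporal_parameters")
}

# signed frame counts of the seven parameters, in PHASE_NAMES order
phase_frame_counts <- function(events) {
  with(events, c(
    OPD = bolus_past_mandible - oral_start,
    PDT = hyoid_burst - bolus_past_mandible,
    PRT = ues_closure - hyoid_burst,
    PTT = ues_closure - bolus_past_mandible,
    LVCRT = lvc_onset - hyoid_burst,
    LVC_DURATION = lvc_offset - lvc_onset,
    UESOD = ues_closure - ues_opening
  ))
}

#' @export
print.temporal_parameters <- function(x, ...) {
  cat("<temporal_parameters>", x$clip_id, sprintf("@ %g fps\n", x$fps))
  nm <- c("opd_ms", "pdt_ms", "prt_ms", "ptt_ms", "lvcrt_ms", "lvcd_ms", "uesod_ms")
  for (n in nm) cat(sprintf("  %-9s %9.2f ms\n", toupper(sub("_ms$", "", n)), x[[n]]))
  invisible(x)
}

# start/end event names per phase, half-open [start, end)
.phase_endpoints <- list(
  OPD = c("oral_start", "bolus_past_mandible"),
  PDT = c("bolus_past_mandible", "hyoid_burst"),
  PRT = c("hyoid_burst", "ues_closure"),
  PTT = c("bolus_past_mandible", "ues_closure"),
  LVCRT = c("hyoid_burst", "lvc_onset"),
  LVC_DURATION = c("lvc_onset", "lvc_offset"),
  UESOD = c("ues_opening", "ues_closure")
)

#' Frame interval occupied by a phase
#'
#' Returns the half-open frame span `[start, end)` of a phase: frame `k` is in
#' the phase iff `start <= k < end`. Events mark "the first frame in which"
#' something happens, which maps to inclusive starts and exclusive ends, so
#' adjacent phases partition frames without double counting. For the two
#' phases whose end event can precede their start event (PDT, LVCRT) the span
#' is `[min, max)` with `reversed = TRUE`; the signed duration is still
#' available from [compute_parameters()].
#'
#' @param events a valid [event_set()].
#' @param phase one of [PHASE_NAMES].
#' @return a list with `phase`, `start`, `end` (exclusive), `reversed`.
#' @export
events_to_phase_interval <- function(events, phase) {
  validate_event_set(events)
  if (!is.character(phase) || length(phase) != 1L || !phase %in% PHASE_NAMES) {
    stop("unknown phase '", paste(phase, collapse = ","), "'; must be one of: ",
         paste(PHASE_NAMES, collapse = ", "))
  }
  ep <- .phase_endpoints[[phase]]
  a <- events[[ep[1]]]
  b <- events[[ep[2]]]
  list(phase = phase, start = min(a, b), end = max(a, b), reversed = b < a)
}

#' Read swallowing-event annotations from CSV or JSON
#'
#' The CSV format has header `clip_id` plus the seven event columns of
#' [EVENT_NAMES], 0-based frame indices; JSON is an array of objects with the
#' same fields. Every record is validated on read; errors report the offending
#' row.
#'
#' @param path file path ending in `.csv` or `.json`.
#' @return a list of [event_set()] objects.
#' @export
read_annotations <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  missing <- setdiff(c("clip_id", EVENT_NAMES), names(df))
  if (length(missing)) {
    stop("annotation file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (nm in EVENT_NAMES) {
    v <- df[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v != floor(v))) {
      stop("annotation file '", path, "': column '", nm,
           "' contains a non-integer frame index")
    }
  }
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    out[[i]] <- tryCatch(
      event_set(df$clip_id[i], df$oral_start[i], df$bolus_past_mandible[i],
                df$hyoid_burst[i], df$lvc_onset[i], df$ues_opening[i],
                df$ues_closure[i], df$lvc_offset[i],
                clip_length = if ("clip_length" %in% names(df)) df$clip_length[i] else NULL),
      error = function(e) stop("annotation file '", path, "', row ", i, ": ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  out
}

#' @rdname read_annotations
#' @param events a list of `event_set` objects (or a single one).
#' @export
write_annotations <- function(events, path) {
  if (inherits(events, "event_set")) events <- list(events)
  df <- annotations_to_df(events)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  } else {
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

annotations_to_df <- function(events) {
  has_len <- all(vapply(events, function(e) !is.null(e$clip_length), logical(1)))
  df <- data.frame(
    clip_id = vapply(events, `[[`, character(1), "clip_id"),
    stringsAsFactors = FALSE
  )
  for (nm in EVENT_NAMES) df[[nm]] <- vapply(events, `[[`, integer(1), nm)
  if (has_len) df$clip_length <- vapply(events, `[[`, integer(1), "clip_length")
  df
}

#' Per-clip temporal parameter report
#'
#' @param events a list of [event_set()] objects.
#' @param fps frames per second.
#' @return a data.frame with one row per clip: the seven parameters in
#'   milliseconds plus `fps`.
#' @export
parameter_report <- function(events, fps) {
  if (inherits(events, "event_set")) events <- list(events)
  rows <- lapply(events, function(e) {
    p <- compute_parameters(e, fps)
    data.frame(clip_id = e$clip_id, opd_ms = p$opd_ms, pdt_ms = p$pdt_ms,
               prt_ms = p$prt_ms, ptt_ms = p$ptt_ms, lvcrt_ms = p$lvcrt_ms,
               lvcd_ms = p$lvcd_ms, uesod_ms = p$uesod_ms, fps = fps,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
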