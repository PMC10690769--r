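#' Read and write traces and event stores
#'
#' On-disk persistence for the two pipeline artefacts: raw traces and
#' extracted-event collections. Both are stored as single-file JSON
#' containers with a stamped schema version and a hierarchical layout
#' (`trace/samples`, `trace/attrs`, `events/*`, `provenance/*`). Numbers
#' are written with 17 significant digits, which round-trips IEEE doubles
#' exactly, so write-then-read is bit-exact for samples, metadata and
#' provenance (numeric metadata is restored as double, JSON's only numeric
#' type).
#'
#' @param trace a [trace_record()].
#' @param path file path.
#' @return `read_trace()` returns a [trace_record()]; the writers return
#'   `path` invisibly.
#' @examples
#' tr <- trace_record(c(5, 5, 4.5, 5), 1e6, list(I0 = 5))
#' f <- tempfile(fileext = ".json")
#' write_trace(tr, f)
#' identical(read_trace(f)$samples, tr$samples)
#' @name trace_io
NULL

SCHEMA_TRACE <- "oligopore-trace-1"
SCHEMA_EVENTS <- "oligopore-events-1"

to_json_file <- function(obj, path) {
  txt <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                          null = "null", na = "null")
  writeLines(txt, path)
  invisible(path)
}

from_json_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
    error = function(e) stop("malformed container ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!is.list(out)) stop("malformed container ", path, call. = FALSE)
  out
}

# JSON does not distinguish 5 from 5.0: restore whole-number scalars as
# double so numeric metadata/provenance round-trips identically
denumber <- function(x) {
  if (is.list(x)) lapply(x, denumber)
  else if (is.integer(x)) as.double(x)
  else x
}

need_field <- function(x, field, where) {
  if (is.null(x[[field]]))
    stop("schema error in ", where, ": missing field '", field, "'",
         call. = FALSE)
  x[[field]]
}

#' @rdname trace_io
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trace_record"))
  to_json_file(list(
    schema = SCHEMA_TRACE,
    trace = list(samples = trace$samples,
                 sampling_rate = trace$sampling_rate,
                 attrs = trace$metadata)
  ), path)
}

#' @rdname trace_io
#' @export
read_trace <- function(path) {
  obj <- from_json_file(path)
  if (!identical(obj$schema, SCHEMA_TRACE))
    stop("schema error in ", path, ": not an ", SCHEMA_TRACE, " file",
         call. = FALSE)
  tr <- need_field(obj, "trace", path)
  samples <- need_field(tr, "samples", path)
  rate <- need_field(tr, "sampling_rate", path)
  meta <- if (is.null(tr$attrs)) list() else denumber(tr$attrs)
  trace_record(as.numeric(samples), as.numeric(rate), metadata = meta)
}

#' Ordered collection of translocation events
#'
#' An `event_store` couples a sorted, non-overlapping list of
#' [event_record()]s (with any decode results they carry) to the provenance
#' of their extraction: source trace id, detector thresholds and software
#' version. When the provenance records the detector thresholds, every
#' stored event is checked against them.
#'
#' @param events list of [event_record()]s.
#' @param provenance named list; recognised fields include `source`,
#'   `min_duration_s`, `min_drop_nA`, `software_version`.
#' @return An object of class `event_store`.
#' @seealso [write_events()], [read_events()]
#' @export
event_store <- function(events = list(), provenance = list()) {
  stopifnot(is.list(events), is.list(provenance))
  for (ev in events) {
    if (!inherits(ev, "event_record"))
      stop("all events must be event_record objects", call. = FALSE)
  }
  if (length(events) > 1L) {
    xl <- vapply(events, `[[`, 1L, "x_left")
    xr <- vapply(events, `[[`, 1L, "x_right")
    if (is.unsorted(xl, strictly = TRUE) || any(xl[-1] < xr[-length(xr)]))
      stop("events must be sorted by start and non-overlapping", call. = FALSE)
  }
  if (!is.null(provenance$min_duration_s) || !is.null(provenance$min_drop_nA)) {
    for (ev in events) {
      ok_dur <- is.null(provenance$min_duration_s) ||
        ev$duration_s >= provenance$min_duration_s
      ok_drop <- is.null(provenance$min_drop_nA) ||
        (ev$I0_local - ev$min_current) >= provenance$min_drop_nA
      if (!ok_dur || !ok_drop)
        stop("stored event [", ev$x_left, ", ", ev$x_right,
             ") violates the provenance thresholds", call. = FALSE)
    }
  }
  structure(list(events = events, provenance = provenance),
            class = "event_store")
}

#' @export
print.event_store <- function(x, ...) {
  cat(sprintf("<event_store> %d events\n", length(x$events)))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.event_store <- function(x) length(x$events)

# optional decode fields serialized with each event
EVENT_EXTRA_FIELDS <- c("category", "bits", "orientation", "class_id",
                        "ecd", "bit_confidence")

#' Write or read an event store
#'
#' Serializes an [event_store()] (events, decode results, provenance) to a
#' single JSON file; `read_events()` restores it exactly, including category
#' labels, barcode reads, ECDs and provenance thresholds.
#'
#' @param store an [event_store()].
#' @param path file path.
#' @return `read_events()` returns an [event_store()]; `write_events()`
#'   returns `path` invisibly.
#' @export
write_events <- function(store, path) {
  stopifnot(inherits(store, "event_store"))
  evs <- lapply(store$events, function(ev) {
    keep <- c("x_left", "x_right", "samples", "I0_local", "sampling_rate",
              EVENT_EXTRA_FIELDS)
    e <- ev[intersect(keep, names(ev))]
    e[!vapply(e, is.null, TRUE)]
  })
  to_json_file(list(schema = SCHEMA_EVENTS, provenance = store$provenance,
                    events = evs), path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  obj <- from_json_file(path)
  if (!identical(obj$schema, SCHEMA_EVENTS))
    stop("schema error in ", path, ": not an ", SCHEMA_EVENTS, " file",
         call. = FALSE)
  prov <- if (is.null(obj$provenance)) list() else denumber(obj$provenance)
  evs <- lapply(obj$events, function(e) {
    for (f in c("x_left", "x_right", "samples", "I0_local", "sampling_rate"))
      need_field(e, f, path)
    extra <- e[intersect(EVENT_EXTRA_FIELDS, names(e))]
    extra <- lapply(extra, function(v)
      if (is.list(v)) unlist(v) else v)
    do.call(event_record, c(list(
      x_left = e$x_left, x_right = e$x_right,
      samples = as.numeric(e$samples),
      I0_local = as.numeric(e$I0_local),
      sampling_rate = as.numeric(e$sampling_rate)), extra))
  })
  event_store(evs, prov)
}
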