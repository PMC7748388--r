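#' Calculation record for the local history store
#'
#' A persisted snapshot of one calculation: the free-text patient identifier
#' (a patient ID number, a nickname, or anything easy to remember — the
#' documentation advises pseudonyms), the full inputs, and the resulting
#' recommendation. Records live only in a local JSON-lines file; no
#' operation in this module ever touches the network.
#'
#' @param patient_id Non-empty free-text identifier.
#' @param inputs Named list snapshot of the inputs (demographics, css, rrt).
#' @param recommendation A `dose_recommendation` (or an equivalent list).
#' @param timestamp ISO-8601 UTC timestamp string; defaults to now.
#' @return An object of class `calculation_record`.
#' @export
calculation_record <- function(patient_id, inputs, recommendation,
                               timestamp = format(Sys.time(),
                                                  "%Y-%m-%dT%H:%M:%SZ",
                                                  tz = "UTC")) {
  if (!is.character(patient_id) || length(patient_id) != 1L ||
      is.na(patient_id) || !nzchar(trimws(patient_id))) {
    stop("'patient_id' must be a non-empty string", call. = FALSE)
  }
  structure(list(patient_id = patient_id,
                 timestamp = timestamp,
                 inputs = inputs,
                 recommendation = unclass(recommendation),
                 app_version = as.character(
                   utils::packageVersion("colidose"))),
            class = "calculation_record")
}

# one JSON line per record; digits = NA keeps full numeric precision so that
# serialize -> deserialize round-trips
.record_to_json <- function(record) {
  jsonlite::toJSON(unclass(record), auto_unbox = TRUE, digits = NA,
                   null = "null")
}

.record_from_json <- function(line, path) {
  rec <- tryCatch(
    jsonlite::fromJSON(line, simplifyVector = TRUE, simplifyDataFrame = FALSE),
    error = function(e) {
      stop("corrupt history store '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (!is.list(rec) || is.null(rec$patient_id)) {
    stop("corrupt history store '", path, "': line is not a calculation ",
         "record", call. = FALSE)
  }
  structure(rec, class = "calculation_record")
}

.read_store <- function(store_path) {
  if (!file.exists(store_path)) return(list())
  lines <- readLines(store_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, .record_from_json, path = store_path)
}

#' Save a calculation record to the local history store
#'
#' Appends the record as one JSON line and assigns it the next id (unique
#' and monotonically increasing within the store). Storage is a plain local
#' file: private, greppable, and permanently deletable with
#' [purge_store()].
#'
#' @param record A [calculation_record()].
#' @param store_path Path to the JSON-lines history file; created if absent.
#' @return The assigned integer record id, invisibly.
#' @export
save_record <- function(record, store_path) {
  stopifnot(inherits(record, "calculation_record"))
  existing <- .read_store(store_path)
  ids <- vapply(existing, function(r) as.integer(r$id %||% 0L), 0L)
  record$id <- if (length(ids)) max(ids) + 1L else 1L
  con <- tryCatch(suppressWarnings(file(store_path, open = "a")),
                  error = function(e) {
                    stop("cannot write history store '", store_path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  on.exit(close(con))
  writeLines(.record_to_json(record), con)
  invisible(record$id)
}

#' List calculation records, newest first
#'
#' @param store_path Path to the history file; a missing store yields an
#'   empty list.
#' @param patient_id Optional filter on the exact patient identifier.
#' @return List of `calculation_record` objects, newest first.
#' @export
list_records <- function(store_path, patient_id = NULL) {
  records <- .read_store(store_path)
  if (!is.null(patient_id)) {
    records <- Filter(function(r) identical(r$patient_id, patient_id),
                      records)
  }
  rev(records)
}

#' Permanently delete the history store
#'
#' Removes the store file; the deletion is unrecoverable by this package.
#' Idempotent on a missing store.
#'
#' @param store_path Path to the history file.
#' @return Number of records deleted.
#' @export
purge_store <- function(store_path) {
  n <- length(.read_store(store_path))
  if (file.exists(store_path)) unlink(store_path)
  n
}
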