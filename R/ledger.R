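#' A local accession ledger
#'
#' Assigns GCST-style accession tokens, records content-addressed dataset
#' versions, and keeps retraction tombstones. The ledger persists as an
#' append-only JSON-lines operation log; opening a ledger replays the log, so
#' the on-disk file is the single source of truth and the full history
#' (including retracted entries) always remains resolvable.
#'
#' This is a *local* stand-in for a central repository's accessioning
#' service: the tokens are format-compatible with repository accessions but
#' are namespaced as locally assigned in any metadata that records them.
#'
#' @param path path to the JSON-lines log (created on first operation).
#' @return An `accession_ledger` handle. Operations mutate the underlying
#'   log and the handle's state in place.
#' @examples
#' led <- ledger_open(tempfile(fileext = ".jsonl"))
#' acc <- assign_accession(led)
#' register_version(led, acc, digest = "d41d8cd98f00b204e9800998ecf8427e")
#' accession_status(led, acc)$status
#' @export
ledger_open <- function(path) {
  env <- new.env(parent = emptyenv())
  env$entries <- list()
  env$next_serial <- 1L
  led <- structure(list(path = path, state = env), class = "accession_ledger")
  if (file.exists(path)) {
    for (line in readLines(path, warn = FALSE)) {
      if (!nzchar(line)) next
      ledger_apply(led, jsonlite::fromJSON(line, simplifyVector = TRUE))
    }
  }
  led
}

ledger_apply <- function(ledger, op) {
  env <- ledger$state
  switch(op$op,
    assign = {
      env$entries[[op$accession]] <- list(
        status = "active", versions = list(), retraction_reason = NULL)
      env$next_serial <- max(env$next_serial, as.integer(op$serial) + 1L)
    },
    version = {
      e <- env$entries[[op$accession]]
      e$versions[[length(e$versions) + 1L]] <- list(
        version = as.integer(op$version), digest = op$digest, timestamp = op$timestamp)
      env$entries[[op$accession]] <- e
    },
    retract = {
      e <- env$entries[[op$accession]]
      e$status <- "retracted"
      e$retraction_reason <- op$reason
      env$entries[[op$accession]] <- e
    },
    stopf("sumstatr_ledger_error", "unknown ledger operation '%s'", op$op)
  )
  invisible(ledger)
}

ledger_append <- function(ledger, op) {
  line <- jsonlite::toJSON(op, auto_unbox = TRUE)
  con <- file(ledger$path, open = "at")
  on.exit(close(con), add = TRUE)
  writeLines(line, con)
  invisible(ledger)
}

ledger_timestamp <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
}

#' @rdname ledger_open
#' @param ledger an `accession_ledger`.
#' @export
ledger_accessions <- function(ledger) names(ledger$state$entries)

#' Assign a new accession
#'
#' Returns the next `"GCST"` + zero-padded serial (six or more digits).
#' Tokens are unique and strictly increasing, numerically and
#' lexicographically. The log line is written before the in-memory state is
#' updated, so a persistence failure consumes no serial.
#'
#' @param ledger an `accession_ledger` from [ledger_open()].
#' @return The accession token, invisibly usable as a plain string.
#' @export
assign_accession <- function(ledger) {
  stopifnot(inherits(ledger, "accession_ledger"))
  serial <- ledger$state$next_serial
  accession <- sprintf("GCST%06d", serial)
  op <- list(op = "assign", accession = accession, serial = serial,
             timestamp = ledger_timestamp())
  ledger_append(ledger, op)
  ledger_apply(ledger, op)
  accession
}

#' Register a dataset version
#'
#' Appends the next version number for an accession, with a content digest
#' (see [sumstats_digest()]) and timestamp. Version numbers within an entry
#' are contiguous from 1; the latest version is what resolvers should serve.
#' Retracted accessions accept no new versions.
#'
#' @inheritParams assign_accession
#' @param accession an accession known to the ledger.
#' @param digest content digest of the canonical serialized dataset bytes.
#' @return The new version number.
#' @export
register_version <- function(ledger, accession, digest) {
  entry <- ledger_entry(ledger, accession)
  if (entry$status == "retracted") {
    stopf("sumstatr_ledger_error",
          "accession %s is retracted and accepts no new versions", accession,
          code = "LIFECYCLE_RETRACTED")
  }
  version <- length(entry$versions) + 1L
  op <- list(op = "version", accession = accession, version = version,
             digest = digest, timestamp = ledger_timestamp())
  ledger_append(ledger, op)
  ledger_apply(ledger, op)
  version
}

#' @rdname register_version
#' @export
latest_version <- function(ledger, accession) {
  entry <- ledger_entry(ledger, accession)
  length(entry$versions)
}

#' Retract an accession
#'
#' Marks the entry retracted while keeping the accession, its metadata and
#' its full version history resolvable — resolution responses carry the
#' retraction indication and reason. Retracting twice is idempotent (with a
#' warning).
#'
#' @inheritParams register_version
#' @param reason free-text retraction reason.
#' @return The tombstone record: list with `accession`, `status`, `reason`,
#'   `versions`.
#' @export
retract_accession <- function(ledger, accession, reason) {
  entry <- ledger_entry(ledger, accession)
  if (entry$status == "retracted") {
    warn(sprintf("accession %s is already retracted", accession))
  } else {
    op <- list(op = "retract", accession = accession, reason = reason,
               timestamp = ledger_timestamp())
    ledger_append(ledger, op)
    ledger_apply(ledger, op)
  }
  accession_status(ledger, accession)
}

ledger_entry <- function(ledger, accession) {
  stopifnot(inherits(ledger, "accession_ledger"))
  entry <- ledger$state$entries[[accession]]
  if (is.null(entry)) {
    stopf("sumstatr_ledger_error", "unknown accession '%s'", accession)
  }
  entry
}

#' Resolve an accession
#'
#' @inheritParams register_version
#' @return list with `accession`, `status` (`active`/`retracted`), `reason`
#'   (retraction reason or `NULL`), `latest` version number, and the
#'   `versions` history.
#' @export
accession_status <- function(ledger, accession) {
  entry <- ledger_entry(ledger, accession)
  list(
    accession = accession,
    status = entry$status,
    reason = entry$retraction_reason,
    latest = length(entry$versions),
    versions = entry$versions
  )
}

#' @export
print.accession_ledger <- function(x, ...) {
  cat(sprintf("# Accession ledger at %s: %d entr%s, next serial %d\n",
              x$path, length(x$state$entries),
              if (length(x$state$entries) == 1L) "y" else "ies",
              x$state$next_serial))
  invisible(x)
}
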