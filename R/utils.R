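#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Shortest decimal string that round-trips to exactly `x` (per element).
# Used for all non-p numeric emission so write -> read is bit-exact.
fmt_double <- function(x) {
  out <- rep(NA_character_, length(x))
  todo <- which(!is.na(x))
  for (d in 1:17) {
    if (length(todo) == 0L) break
    cand <- sprintf("%.*g", d, x[todo])
    ok <- as.numeric(cand) == x[todo]
    out[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  out
}

# Positions emitted without decimals when integral.
fmt_position <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  intish <- ok & is.finite(x) & x == floor(x)
  out[intish] <- sprintf("%.0f", x[intish])
  rest <- ok & !intish
  out[rest] <- fmt_double(x[rest])
  out
}

new_issues <- function(severity = character(), code = character(),
                       row = integer(), column = character(),
                       message = character(), observed = character()) {
  tibble(
    severity = as.character(severity),
    code = as.character(code),
    row = as.integer(row),
    column = as.character(column),
    message = as.character(message),
    observed = as.character(observed)
  )
}

issue <- function(severity, code, row, column, message, observed = NA_character_) {
  new_issues(severity, code, row, column, message, observed)
}

bind_issues <- function(...) {
  out <- dplyr::bind_rows(...)
  if (nrow(out) == 0L) return(new_issues())
  dplyr::arrange(out, .data$row, .data$column, .data$code)
}

stopf <- function(class, ..., code = NULL) {
  abort(sprintf(...), class = c(class, "sumstatr_error"), code = code)
}
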