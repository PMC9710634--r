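#' Communication log for simulated federation traffic
#'
#' Every parameter exchange between a client and the aggregator is recorded as
#' one message with its payload shape; the log is the ground truth that the
#' closed-form cost model ([predicted_comm_cost()]) is checked against. A log
#' is an environment, so the same object can be threaded through client and
#' aggregator code and appended to in place.
#'
#' Derived totals: `comm_total()` is T, the total number of transmitted
#' scalars; `comm_rounds()` is N, the number of distinct communication rounds
#' (several messages sent in parallel share one round).
#'
#' @return `comm_log()` returns an empty log of class `comm_log`.
#' @seealso [record_message()], [write_comm_log()]
#' @examples
#' log <- comm_log()
#' record_message(log, round = 1, sender = 1, receiver = "aggregator",
#'                rows = 10, cols = 4)
#' comm_total(log)
#' @export
comm_log <- function() {
  env <- new.env(parent = emptyenv())
  env$records <- list()
  class(env) <- "comm_log"
  env
}

#' Append one message record to a communication log
#'
#' @param log A [comm_log()].
#' @param round Nonnegative integer round counter. Uploads that happen in
#'   parallel (all clients to the aggregator) share a round.
#' @param sender,receiver Site index (integer) or the string `"aggregator"`.
#'   Must differ.
#' @param rows,cols Payload shape; `rows * cols` scalars are counted.
#' @return The log, invisibly (it is modified in place).
#' @export
record_message <- function(log, round, sender, receiver, rows, cols) {
  stopifnot(inherits(log, "comm_log"))
  if (!(length(round) == 1L && is.numeric(round) && round >= 0 && round == floor(round)))
    .stopf("`round` must be a nonnegative integer")
  if (!.is_count(rows) || !.is_count(cols))
    .stopf("payload shape must be positive integers (got %s x %s)",
           deparse(rows), deparse(cols))
  sender <- as.character(sender); receiver <- as.character(receiver)
  if (identical(sender, receiver))
    .stopf("sender and receiver must differ (both '%s')", sender)
  log$records[[length(log$records) + 1L]] <- list(
    round = as.integer(round), sender = sender, receiver = receiver,
    rows = as.integer(rows), cols = as.integer(cols),
    scalar_count = as.numeric(rows) * as.numeric(cols))
  invisible(log)
}

#' @rdname comm_log
#' @param log A `comm_log`.
#' @export
comm_total <- function(log) {
  stopifnot(inherits(log, "comm_log"))
  sum(vapply(log$records, `[[`, numeric(1), "scalar_count"))
}

#' @rdname comm_log
#' @export
comm_rounds <- function(log) {
  stopifnot(inherits(log, "comm_log"))
  length(unique(vapply(log$records, `[[`, integer(1), "round")))
}

#' @export
as.data.frame.comm_log <- function(x, ...) {
  if (!length(x$records))
    return(data.frame(round = integer(), sender = character(),
                      receiver = character(), rows = integer(),
                      cols = integer(), scalar_count = numeric()))
  do.call(rbind, lapply(x$records, function(r)
    data.frame(round = r$round, sender = r$sender, receiver = r$receiver,
               rows = r$rows, cols = r$cols, scalar_count = r$scalar_count)))
}

#' @export
print.comm_log <- function(x, ...) {
  cat(sprintf("<comm_log> %d messages, %d rounds, %s scalars transmitted\n",
              length(x$records), comm_rounds(x), format(comm_total(x))))
  invisible(x)
}

#' Export a communication log as JSON
#'
#' Writes the records as a JSON array with keys `round`, `sender`,
#' `receiver`, `rows`, `cols`, `scalar_count`.
#'
#' @param log A [comm_log()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_comm_log <- function(log, path) {
  jsonlite::write_json(as.data.frame(log), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.AGG <- "aggregator"
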