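#' Injectable clock
#'
#' All time-dependent agents (sessions, scheduler, processor heartbeats,
#' ledger timestamps) read the current time from a clock object rather than
#' calling `Sys.time()` directly, so tests and simulations can drive a fake
#' clock deterministically.
#'
#' @param start `NULL` for a real (wall) clock, or a POSIXct/parsable string
#'   for a fake clock that only moves when `$advance()` is called.
#' @return a `Clock` R6 object with methods `now()`, `now_iso()`,
#'   `advance(seconds)` (fake clocks only) and field `is_fake`.
#' @examples
#' cl <- sandbox_clock("2024-01-01 00:00:00")
#' cl$advance(60)
#' cl$now_iso()
#' @export
sandbox_clock <- function(start = NULL) {
  Clock$new(start)
}

#' @rdname sandbox_clock
#' @export
fake_clock <- function(start = "2024-01-01 00:00:00") {
  sandbox_clock(start = start)
}

Clock <- R6::R6Class("Clock",
  public = list(
    is_fake = FALSE,
    initialize = function(start = NULL) {
      if (!is.null(start)) {
        if (is.character(start)) start <- as.POSIXct(start, tz = "UTC")
        private$t <- as.POSIXct(start, tz = "UTC")
        self$is_fake <- TRUE
      }
    },
    now = function() {
      if (self$is_fake) private$t else Sys.time()
    },
    now_iso = function() iso8601(self$now()),
    advance = function(seconds) {
      if (!self$is_fake) {
        stop_sandbox("sandbox_contract_error", "cannot advance a real clock")
      }
      private$t <- private$t + seconds
      invisible(self$now())
    }
  ),
  private = list(t = NULL)
)
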