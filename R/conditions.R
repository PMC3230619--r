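## Classed conditions so the command-line interface can map failures to exit
## codes (usage vs I/O vs numerical) without string-matching messages.

stopWithClass <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "bioturb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stopUsage   <- function(fmt, ...) stopWithClass("bioturb_usage_error", fmt, ...)
stopIO      <- function(fmt, ...) stopWithClass("bioturb_io_error", fmt, ...)
stopNumeric <- function(fmt, ...) stopWithClass("bioturb_numeric_error", fmt, ...)

## Internal-consistency failures (a bug, not a user error).
stopInternal <- function(fmt, ...) stopWithClass("bioturb_internal_error", fmt, ...)
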