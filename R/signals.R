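#' Signal programs
#'
#' Exogenous trajectories bound to signalling nodes during simulation.
#' Conditions are expressed by giving each signal a program: a constant
#' level (e.g., sustained stimulation, or 0 for knock-down of the
#' signal's targets' input), a periodic waveform (e.g., repeated drug
#' administration), or arbitrary sampled values interpolated linearly.
#' All programs are non-negative over the whole simulation interval.
#'
#' @param value constant level (>= 0).
#' @param amplitude peak level of the periodic waveform (>= 0).
#' @param period waveform period (time units, > 0).
#' @param waveform \code{"sine"} (raised sine in [0, amplitude]) or
#'   \code{"square"} (on for the first half-period).
#' @param time,values sample points for a custom program.
#' @return an object of class \code{signal_program}.
#' @name signal_programs
#' @examples
#' signal_constant(1)
#' signal_periodic(1, period = 10, waveform = "square")
NULL

new_signal_program <- function(type, fn, spec) {
  structure(list(type = type, fn = fn, spec = spec),
            class = "signal_program")
}

#' @rdname signal_programs
#' @export
signal_constant <- function(value) {
  if (value < 0) stop("signal values must be >= 0")
  force(value)
  new_signal_program("constant", function(t) rep(value, length(t)),
                     list(value = value))
}

#' @rdname signal_programs
#' @export
signal_zero <- function() signal_constant(0)

#' @rdname signal_programs
#' @export
signal_periodic <- function(amplitude, period, waveform = c("sine", "square")) {
  waveform <- match.arg(waveform)
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (period <= 0) stop("period must be > 0")
  fn <- if (waveform == "sine") {
    function(t) amplitude * (1 + sin(2 * pi * t / period)) / 2
  } else {
    function(t) amplitude * as.numeric((t %% period) < period / 2)
  }
  new_signal_program("periodic", fn,
                     list(amplitude = amplitude, period = period,
                          waveform = waveform))
}

#' @rdname signal_programs
#' @export
signal_custom <- function(time, values) {
  if (any(values < 0)) stop("signal values must be >= 0")
  fn <- approxfun(time, values, rule = 2)
  new_signal_program("custom", fn, list(time = time, values = values))
}

#' @export
print.signal_program <- function(x, ...) {
  cat("signal_program:", x$type, "\n")
  invisible(x)
}

## Resolve a signals argument into one program per signal node.
## Accepts: NULL (all zero), a single program (recycled), or a named
## list keyed by signal name (missing names default to zero).
resolve_signal_programs <- function(signal_names, signals) {
  if (is.null(signals)) signals <- signal_zero()
  if (inherits(signals, "signal_program"))
    return(setNames(rep(list(signals), length(signal_names)), signal_names))
  stopifnot(is.list(signals))
  out <- setNames(vector("list", length(signal_names)), signal_names)
  unknown <- setdiff(names(signals), signal_names)
  if (length(unknown))
    stop("unknown signal name(s): ", paste(unknown, collapse = ", "))
  for (nm in signal_names)
    out[[nm]] <- if (!is.null(signals[[nm]])) signals[[nm]] else signal_zero()
  out
}

## Vector of signal values at time t, in the given order.
signal_values_at <- function(programs, t) {
  vapply(programs, function(p) p$fn(t), numeric(1))
}
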