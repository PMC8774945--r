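# Learning-rate schedules for the stochastic-approximation updates.

#' Learning-rate schedules
#'
#' Three schedule families cover the benchmark experimental settings:
#' constant `c`; power `t^(-r)`; and floored power `max(t^(-r), c)`.
#' Iteration indexing starts at `t = 1`.
#'
#' @param c positive constant rate / floor.
#' @param r positive decay exponent.
#' @return An object of class `lr_schedule`: call it with an iteration index
#'   (vectorised) to obtain the step size.
#' @examples
#' eta <- lr_floored_power(0.1, 0.2)  # max(t^-0.1, 0.2)
#' eta(c(1, 10, 1e7))
#' @export
lr_constant <- function(c) {
  stopifnot(c >= 0)
  structure(function(t) rep_len(c, length(t)),
            class = "lr_schedule", spec = sprintf("const:%g", c))
}

#' @rdname lr_constant
#' @export
lr_power <- function(r) {
  stopifnot(r > 0)
  structure(function(t) t^(-r),
            class = "lr_schedule", spec = sprintf("pow:%g", r))
}

#' @rdname lr_constant
#' @export
lr_floored_power <- function(r, c) {
  stopifnot(r > 0, c > 0)
  structure(function(t) pmax(t^(-r), c),
            class = "lr_schedule", spec = sprintf("fpow:%g,%g", r, c))
}

#' Parse a learning-rate specification string
#'
#' Accepts `"const:c"`, `"pow:r"` and `"fpow:r,c"` (the CLI syntax), a bare
#' number (treated as a constant rate), or an existing schedule.
#'
#' @param spec specification.
#' @return An `lr_schedule`.
#' @export
parse_lr <- function(spec) {
  if (inherits(spec, "lr_schedule")) return(spec)
  if (is.numeric(spec)) return(lr_constant(spec))
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("learning-rate spec must look like kind:values")
  vals <- as.numeric(strsplit(parts[2], ",", fixed = TRUE)[[1]])
  switch(parts[1],
    const = lr_constant(vals[1]),
    pow = lr_power(vals[1]),
    fpow = lr_floored_power(vals[1], vals[2]),
    stop(sprintf("unknown learning-rate kind '%s'", parts[1]))
  )
}

#' @export
print.lr_schedule <- function(x, ...) {
  cat("learning-rate schedule", attr(x, "spec"), "\n")
  invisible(x)
}
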