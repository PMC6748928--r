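# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bad_arg(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    stop_bad_arg(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0)
    stop_bad_arg(sprintf("`%s` must be >= 0", name))
  invisible(x)
}

#' Wrap angles to the half-open interval (-180, 180] degrees
#'
#' Relative turning angles use the convention that a full reversal maps to
#' +180 degrees (never -180), so the wrap is half-open.
#'
#' @param a numeric vector of angles in degrees.
#' @return numeric vector in (-180, 180].
#' @keywords internal
#' @noRd
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

# Euclidean distance from each row of `xy` (n x 2) to point `p` (length 2)
dist_to_point <- function(xy, p) {
  sqrt((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2)
}

# epoch origin used by the simulator and tests
.sim_origin <- function() as.POSIXct("2010-05-01 00:00:00", tz = "UTC")
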