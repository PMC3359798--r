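#' Concentration-time curve
#'
#' Container for one voxel's or ROI's sampled gadolinium-induced 1H
#' concentration curve. Times are in minutes, concentrations in mM.
#'
#' @param times Numeric vector of sampling times in minutes; strictly
#'   increasing, first time >= 0.
#' @param values Numeric vector of concentrations in mM, same length as
#'   `times`. Noiseless model curves are nonnegative; measured or
#'   noise-corrupted curves may dip below zero and are accepted.
#' @return An object of class `concentration_curve`: a list with elements
#'   `times` and `values`.
#' @examples
#' concentration_curve(0:5, c(0, 0.1, 0.18, 0.24, 0.28, 0.31))
#' @export
concentration_curve <- function(times, values) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) == 0L)
    stop("a concentration curve needs at least one sample")
  if (length(times) != length(values))
    stop("'times' and 'values' must have the same length")
  if (anyNA(times) || any(!is.finite(times)))
    stop("'times' must be finite")
  if (anyNA(values) || any(!is.finite(values)))
    stop("'values' must be finite")
  if (times[1L] < 0)
    stop("first sampling time must be >= 0")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  structure(list(times = times, values = values),
            class = "concentration_curve")
}

#' @export
print.concentration_curve <- function(x, ...) {
  cat(sprintf("<concentration_curve: %d samples, t = %g..%g min, peak %.4g mM>\n",
              length(x$times), x$times[1L], x$times[length(x$times)],
              max(x$values)))
  invisible(x)
}

#' @export
length.concentration_curve <- function(x) length(x$times)

#' @export
as.data.frame.concentration_curve <- function(x, ...) {
  data.frame(time_min = x$times, conc_mM = x$values)
}

.is_curve <- function(x) inherits(x, "concentration_curve")

.check_curve <- function(curve, n_min = 1L, what = "curve") {
  if (!.is_curve(curve))
    stop(sprintf("'%s' must be a concentration_curve", what))
  if (length(curve$times) < n_min)
    stop(sprintf("'%s' needs at least %d samples, got %d",
                 what, n_min, length(curve$times)))
  invisible(curve)
}
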