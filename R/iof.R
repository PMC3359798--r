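.check_rates <- function(rates) {
  need <- c("subject", "region", "stage", "k_in_prime", "k_out_prime")
  if (!is.data.frame(rates))
    stop("'rates' must be a data.frame of cohort CSF rates")
  miss <- setdiff(need, names(rates))
  if (length(miss))
    stop("missing rate columns: ", paste(miss, collapse = ", "))
  for (col in c("k_in_prime", "k_out_prime")) {
    if (!is.numeric(rates[[col]]) || anyNA(rates[[col]]))
      stop(sprintf("column '%s' must be numeric without missing values", col))
  }
  if (nrow(rates) == 0L) stop("empty rates table")
  rates
}

#' Per-stage mean CSF rates
#'
#' Arithmetic means of the per-subject CSF input (`k_in_prime`, mM/min)
#' and output (`k_out_prime`, 1/min) rates, computed for every
#' (region, stage) group of a cohort. Means are unweighted over subjects.
#'
#' @param rates A data.frame with columns `subject`, `region`, `stage`,
#'   `k_in_prime`, `k_out_prime` (one row per subject, region and stage).
#' @return A data.frame with one row per (region, stage) and columns
#'   `region`, `stage`, `n`, `k_in_prime`, `k_out_prime`.
#' @examples
#' r <- data.frame(subject = c("s1", "s2"), region = "aqueduct",
#'                 stage = "control", k_in_prime = c(0.04, 0.08),
#'                 k_out_prime = c(0.03, 0.03))
#' stage_means(r)   # mean k_in_prime = 0.06
#' @export
stage_means <- function(rates) {
  rates <- .check_rates(rates)
  key <- interaction(rates$region, rates$stage, drop = TRUE, sep = "\r")
  idx <- split(seq_len(nrow(rates)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    data.frame(region = as.character(rates$region[i[1L]]),
               stage = as.character(rates$stage[i[1L]]),
               n = length(i),
               k_in_prime = mean(rates$k_in_prime[i]),
               k_out_prime = mean(rates$k_out_prime[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$region, out$stage), , drop = FALSE]
}

#' Normalize stage means against the control stage
#'
#' Divides each (region, stage) mean input/output rate by the same-region
#' control-stage mean of the same rate type, yielding the dimensionless
#' normalized rates entering the IOF statistic. The control stage itself
#' normalizes to exactly 1.
#'
#' @param means Output of [stage_means()].
#' @param control_stage Label of the control (normal-brain) stage.
#' @return `means` with columns `normalized_in` and `normalized_out`
#'   appended.
#' @export
normalize_to_control <- function(means, control_stage) {
  stopifnot(is.data.frame(means),
            all(c("region", "stage", "k_in_prime", "k_out_prime")
                %in% names(means)))
  if (!is.character(control_stage) || length(control_stage) != 1L ||
      !nzchar(control_stage))
    stop("'control_stage' must be a single non-empty label")
  means$normalized_in <- NA_real_
  means$normalized_out <- NA_real_
  for (reg in unique(means$region)) {
    sel <- means$region == reg
    ctl <- sel & means$stage == control_stage
    if (!any(ctl))
      stop(sprintf("no control stage '%s' for region '%s'",
                   control_stage, reg))
    cin <- means$k_in_prime[ctl][1L]
    cout <- means$k_out_prime[ctl][1L]
    if (cin == 0)
      stop(sprintf("control mean k_in_prime is 0 in region '%s': cannot normalize",
                   reg))
    if (cout == 0)
      stop(sprintf("control mean k_out_prime is 0 in region '%s': cannot normalize",
                   reg))
    means$normalized_in[sel] <- means$k_in_prime[sel] / cin
    means$normalized_out[sel] <- means$k_out_prime[sel] / cout
  }
  means
}

#' Output-to-input flow (IOF) statistic
#'
#' Ratio of the control-normalized mean CSF input rate to the
#' control-normalized mean CSF output rate for each (region, stage):
#' IOF = normalized_in / normalized_out. The control stage has IOF = 1 by
#' construction. IOF > 1 means the disturbance of the input mechanism
#' predominates; IOF < 1 the output mechanism; a configurable tolerance
#' band around 1 is classified "balanced" (the strict binary rule is
#' recovered at `tol = 0`). Whenever IOF < 1 the reciprocal 1/IOF is
#' reported alongside.
#'
#' @param normalized Output of [normalize_to_control()].
#' @param tol Half-width of the "balanced" band around IOF = 1
#'   (default 1e-9).
#' @return A data.frame with columns `region`, `stage`, `normalized_in`,
#'   `normalized_out`, `iof`, `iof_reciprocal` (NA unless IOF < 1) and
#'   `predominance` (one of "input", "output", "balanced").
#' @export
iof <- function(normalized, tol = 1e-9) {
  stopifnot(is.data.frame(normalized),
            all(c("region", "stage", "normalized_in", "normalized_out")
                %in% names(normalized)))
  tol <- .check_scalar(tol, "tol", lower = 0)
  if (any(normalized$normalized_out <= 0))
    stop("normalized_out must be > 0 to form the IOF ratio")
  if (any(normalized$normalized_in < 0))
    stop("normalized_in must be >= 0")
  out <- normalized[, intersect(
    c("region", "stage", "n", "k_in_prime", "k_out_prime",
      "normalized_in", "normalized_out"), names(normalized)), drop = FALSE]
  out$iof <- out$normalized_in / out$normalized_out
  out$iof_reciprocal <- ifelse(out$iof < 1, 1 / out$iof, NA_real_)
  out$predominance <- ifelse(out$iof > 1 + tol, "input",
                       ifelse(out$iof < 1 - tol, "output", "balanced"))
  rownames(out) <- NULL
  out
}

#' Full IOF analysis of a cohort rates table
#'
#' Convenience pipeline: [stage_means()], [normalize_to_control()] and
#' [iof()] applied in sequence.
#'
#' @inheritParams stage_means
#' @inheritParams normalize_to_control
#' @inheritParams iof
#' @return The IOF table (see [iof()]).
#' @export
iof_analysis <- function(rates, control_stage = "control", tol = 1e-9) {
  iof(normalize_to_control(stage_means(rates), control_stage), tol = tol)
}
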