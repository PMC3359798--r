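#' @title Fit result container
#' @description Result of a constrained nonlinear least-squares fit of one
#'   of the kinetic models. `params` holds the estimated parameter object
#'   ([blood_params], [tissue_params] or [csf_params]), which always
#'   satisfies its structural invariants (nonnegative rates, exact volume
#'   closure).
#' @name dcekin_fit
#' @keywords internal
NULL

.fit_result <- function(model, params, rss, converged, n_iter, bounds_hit,
                        message = "", notes = character()) {
  structure(list(model = model, params = params, rss = rss,
                 converged = converged, n_iter = n_iter,
                 bounds_hit = bounds_hit, message = message, notes = notes),
            class = "dcekin_fit")
}

#' @export
print.dcekin_fit <- function(x, ...) {
  cat(sprintf("<dcekin_fit: %s model, rss = %.6g mM^2, %s in %d iterations>\n",
              x$model, x$rss,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(x$params)
  if (length(x$bounds_hit))
    cat("  at bound:", paste(x$bounds_hit, collapse = ", "), "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

# Bounded Levenberg-Marquardt from several deterministic starting points;
# the lowest-RSS solution wins. Convergence tolerances: relative rss
# change < ftol or parameter step < ptol, at most `maxiter` iterations.
.multistart_lm <- function(resid_fn, starts, lower, upper,
                           ftol = 1e-12, ptol = 1e-10, maxiter = 500L) {
  ctrl <- minpack.lm::nls.lm.control(ftol = ftol, ptol = ptol,
                                     maxiter = maxiter)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- pmin(pmax(as.numeric(starts[i, ]), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = lower, upper = upper,
                         fn = resid_fn, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("all optimizer starts failed")
  best
}

.bounds_hit <- function(theta, lower, upper, names, tol = 1e-10) {
  scale <- pmax(abs(upper - lower), 1)
  hit <- (theta - lower) < tol * scale |
    (is.finite(upper) & (upper - theta) < tol * scale)
  names[hit]
}

.check_fit_curve <- function(curve, n_min) {
  .check_curve(curve, n_min = n_min)
  if (all(curve$values == 0))
    stop("degenerate input: curve is identically zero")
  if (max(abs(curve$values)) < .Machine$double.eps)
    stop("degenerate input: curve has no signal")
  invisible(curve)
}

# Estimates below this are reported as exactly 0 1/min (null-rate
# convention for barrier transfer rates).
.RATE_ZERO_TOL <- 1e-6

#' Fit blood-pool parameters to a blood ROI curve
#'
#' Estimates `(c_in, k_out)` of the arterial input model from a measured
#' blood concentration curve by bounded Levenberg-Marquardt least squares,
#' with the hematocrit supplied (not estimated). Starting points are a
#' data-driven guess from the curve peak plus deterministic points spread
#' over physiologically reported ranges.
#'
#' @param curve A [concentration_curve] from a blood ROI (>= 4 samples).
#' @param hct Hematocrit in \[0, 1\].
#' @param ... Optimizer tolerances passed to the internal LM driver
#'   (`ftol`, `ptol`, `maxiter`).
#' @return A `dcekin_fit` whose `params` is a [blood_params].
#' @examples
#' b <- blood_params(0.05, 0.03, 0.45)
#' tt <- seq(0, 60, by = 1)
#' fit <- fit_blood(concentration_curve(tt, blood_concentration(tt, b)), 0.45)
#' fit$params
#' @export
fit_blood <- function(curve, hct, ...) {
  .check_fit_curve(curve, n_min = 4L)
  hct <- .check_scalar(hct, "hct", lower = 0, upper = 1)
  if (hct == 1)
    stop("hct = 1 leaves no plasma signal; blood parameters unidentifiable")
  tt <- curve$times
  yy <- curve$values
  resid_fn <- function(th) {
    bp <- list(c_in = th[1L], k_out = th[2L], hct = hct)
    class(bp) <- "blood_params"
    blood_concentration(tt, bp) - yy
  }
  # data-driven start from the peak of t*exp(-kt): t_peak = 1/k
  ipk <- which.max(yy)
  k0 <- if (tt[ipk] > 0) 1 / tt[ipk] else 0.03
  c0 <- max(yy[ipk], 1e-6) * exp(1) * k0 / (1 - hct)
  starts <- rbind(c(c0, k0),
                  c(0.0427, 0.0281),
                  c(0.0956, 0.0344),
                  c(0.06, 0.031),
                  c(0.02, 0.06))
  lower <- c(0, 1e-6)
  upper <- c(10, 10)
  best <- .multistart_lm(resid_fn, starts, lower, upper, ...)
  th <- best$par
  .fit_result(
    model = "blood",
    params = blood_params(c_in = th[1L], k_out = th[2L], hct = hct),
    rss = best$deviance,
    converged = best$info %in% 1:4,
    n_iter = best$niter,
    bounds_hit = .bounds_hit(th, lower, upper, c("c_in", "k_out")),
    message = best$message)
}

#' Fit tissue-voxel parameters to a tissue curve
#'
#' Two-stage estimation: blood-pool parameters are supplied (fitted first
#' from a blood ROI) and never modified. The free parameters are the four
#' exchange rates plus the blood and IES fractional volumes; `v_ees` is
#' fixed (default 20%) unless `v_ees_fixed = NULL`, in which case it is
#' estimated too but is only weakly identifiable. Volume closure is
#' enforced structurally: the optimizer works on stick-breaking
#' coordinates, so the returned volumes always sum to exactly 1 with
#' `v_now >= 0`.
#'
#' Identifiability: the tissue curve depends on `v_ies` and `k_pi` only
#' through their product (the IES rate equation is linear in `k_pi` and
#' the mixture is linear in `v_ies`), so only `v_ies * k_pi` is determined
#' by the data; the individual values returned lie on that ridge and the
#' result carries a note saying so. `k_trans`, `k_ep`, `k_ip` and
#' `v_blood` are identifiable. A fitted `k_trans` below 1e-6 1/min is
#' reported as exactly 0 and flagged as blood-only enhancement (intact
#' blood-brain barrier).
#'
#' @param curve A [concentration_curve] from a tissue voxel/ROI
#'   (>= 8 samples).
#' @param blood A [blood_params] object from the first stage.
#' @param v_ees_fixed Fractional EES volume to hold fixed (default 0.20),
#'   or `NULL` to estimate it.
#' @param method Forward-model path for the IES term (see
#'   [ies_concentration()]).
#' @param ... Optimizer tolerances (`ftol`, `ptol`, `maxiter`).
#' @return A `dcekin_fit` whose `params` is a [tissue_params]; fields
#'   `blood_only` (logical) and `v_ies_k_pi` (the identifiable product)
#'   are attached to the result.
#' @export
fit_tissue <- function(curve, blood, v_ees_fixed = 0.20,
                       method = "auto", ...) {
  .check_fit_curve(curve, n_min = 8L)
  stopifnot(inherits(blood, "blood_params"))
  free_vees <- is.null(v_ees_fixed)
  if (!free_vees) {
    v_ees_fixed <- .check_scalar(v_ees_fixed, "v_ees_fixed", lower = 0)
    if (v_ees_fixed > 1)
      stop("v_ees_fixed > 1 is infeasible: volumes must close to 1")
  }
  tt <- curve$times
  yy <- curve$values

  # theta: k_trans, k_ep, k_pi, k_ip, u_b, u_i [, v_ees if free]
  # stick-breaking: v_blood = (1 - v_ees) u_b,
  #                 v_ies  = (1 - v_ees - v_blood) u_i, v_now = remainder
  theta_to_params <- function(th) {
    v_ees <- if (free_vees) th[7L] else v_ees_fixed
    v_blood <- (1 - v_ees) * th[5L]
    v_ies <- (1 - v_ees - v_blood) * th[6L]
    p <- list(k_trans = th[1L], k_ep = th[2L], k_pi = th[3L], k_ip = th[4L],
              v_blood = v_blood, v_ees = v_ees, v_ies = v_ies,
              v_now = max(1 - v_blood - v_ees - v_ies, 0))
    class(p) <- "tissue_params"
    p
  }
  resid_fn <- function(th) {
    tissue_concentration(tt, theta_to_params(th), blood, method) - yy
  }
  starts <- rbind(
    c(1e-4, 0.010, 1e-3, 5e-3, 0.03, 0.90),
    c(5e-4, 0.050, 5e-3, 1e-2, 0.06, 0.80),
    c(2e-4, 0.005, 2e-3, 2e-3, 0.12, 0.95),
    c(1e-3, 0.020, 1e-2, 5e-2, 0.01, 0.70),
    c(1e-5, 0.100, 1e-4, 1e-3, 0.25, 0.85))
  nm <- c("k_trans", "k_ep", "k_pi", "k_ip", "u_blood", "u_ies")
  lower <- c(0, 0, 0, 0, 0, 0)
  upper <- c(0.5, 2, 2, 2, 1, 1)
  if (free_vees) {
    starts <- cbind(starts, 0.20)
    nm <- c(nm, "v_ees")
    lower <- c(lower, 0)
    upper <- c(upper, 1)
  }
  best <- .multistart_lm(resid_fn, starts, lower, upper, ...)
  th <- best$par
  # null-rate convention
  th[1:4][th[1:4] < .RATE_ZERO_TOL] <- 0
  params <- theta_to_params(th)
  blood_only <- params$k_trans == 0
  notes <- "v_ies and k_pi are identified only through their product v_ies*k_pi"
  if (blood_only)
    notes <- c(notes,
               "blood-only enhancement: k_trans = 0 (intact blood-brain barrier)")
  res <- .fit_result(
    model = "tissue",
    params = params,
    rss = best$deviance,
    converged = best$info %in% 1:4,
    n_iter = best$niter,
    bounds_hit = .bounds_hit(th, lower, upper, nm),
    message = best$message,
    notes = notes)
  res$blood_only <- blood_only
  res$v_ies_k_pi <- params$v_ies * params$k_pi
  res
}

#' Fit CSF-voxel parameters to a CSF curve
#'
#' Estimates `(k_in_prime, k_out_prime, v_blood)` of the two-compartment
#' CSF voxel model with `v_csf = 1 - v_blood` enforced structurally; the
#' blood-pool parameters come from the first fitting stage and are not
#' modified. When the CSF output rate approaches the blood elimination
#' rate, the blood and CSF input shapes become proportional and
#' `(v_blood, k_in_prime)` collapse toward one identifiable combination;
#' the least-squares optimum then wanders along a flat valley and the two
#' estimates become heavy-tailed. `v_blood_max` caps the blood fraction
#' at a physiological value: the blood compartment in CSF voxels arises
#' from partial-volume contamination of small CSF spaces, with reported
#' fractional volumes well below 30%, so the default bound excludes only
#' non-physiological valley excursions. Set `v_blood_max = 1` for the
#' unconstrained invariant range.
#'
#' @param curve A [concentration_curve] from a CSF voxel/ROI
#'   (>= 4 samples).
#' @param blood A [blood_params] object from the first stage.
#' @param v_blood_max Upper bound for the fractional blood volume
#'   (default 0.3).
#' @param ... Optimizer tolerances (`ftol`, `ptol`, `maxiter`).
#' @return A `dcekin_fit` whose `params` is a [csf_params].
#' @export
fit_csf <- function(curve, blood, v_blood_max = 0.3, ...) {
  .check_fit_curve(curve, n_min = 4L)
  stopifnot(inherits(blood, "blood_params"))
  tt <- curve$times
  yy <- curve$values
  cb <- blood_concentration(tt, blood)
  theta_to_params <- function(th) {
    p <- list(k_in_prime = th[1L], k_out_prime = th[2L],
              v_blood = th[3L], v_csf = 1 - th[3L])
    class(p) <- "csf_params"
    p
  }
  resid_fn <- function(th) {
    th[3L] * cb + (1 - th[3L]) *
      .infusion_shape(tt, th[1L], th[2L]) - yy
  }
  v_blood_max <- .check_scalar(v_blood_max, "v_blood_max",
                               lower = 0, upper = 1)
  ipk <- which.max(yy)
  k0 <- if (tt[ipk] > 0) 1 / tt[ipk] else 0.03
  c0 <- max(yy[ipk], 1e-6) * exp(1) * k0
  starts <- rbind(c(c0, k0, 0.0),
                  c(0.0427, 0.0281, 0.10),
                  c(0.0956, 0.0344, 0.20),
                  c(0.06, 0.031, 0.12),
                  c(0.02, 0.06, 0.30))
  lower <- c(0, 1e-6, 0)
  upper <- c(10, 10, v_blood_max)
  best <- .multistart_lm(resid_fn, starts, lower, upper, ...)
  th <- best$par
  .fit_result(
    model = "csf",
    params = theta_to_params(th),
    rss = best$deviance,
    converged = best$info %in% 1:4,
    n_iter = best$niter,
    bounds_hit = .bounds_hit(th, lower, upper,
                             c("k_in_prime", "k_out_prime", "v_blood")),
    message = best$message)
}
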