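.check_times <- function(t) {
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric (minutes)")
  if (any(t < 0))
    stop("negative times are outside the model domain")
  as.numeric(t)
}

# t * exp(-k * t) input shape, optionally continued past the end of the
# slow infusion (t_end) by pure mono-exponential elimination at rate k,
# continuous at t_end.
.infusion_shape <- function(t, rate_in, k, t_end = Inf) {
  out <- rate_in * t * exp(-k * t)
  if (is.finite(t_end)) {
    late <- t > t_end
    if (any(late)) {
      peak <- rate_in * t_end * exp(-k * t_end)
      out[late] <- peak * exp(-k * (t[late] - t_end))
    }
  }
  out
}

#' Arterial input function
#'
#' Concentration of contrast-affected 1H spins in arterial blood under a
#' slow continuous infusion: AIF(t) = c_in * t * exp(-k_out * t). The
#' expression holds before and during the infusion; past an optional
#' infusion end `t_end` only elimination acts, and the curve is continued
#' as a mono-exponential decay at rate `k_out`, continuous at `t_end`.
#'
#' @param t Time(s) in minutes, >= 0; vectorized.
#' @param blood A [blood_params] object.
#' @param t_end End of the infusion window in minutes; `Inf` (default)
#'   keeps the infusion-phase expression everywhere.
#' @return Concentration(s) in mM.
#' @examples
#' b <- blood_params(0.05, 0.03, 0.45)
#' aif(10, b)               # 0.5 * exp(-0.3)
#' aif(1 / b$k_out, b)      # the unique maximum, c_in/(e * k_out)
#' @export
aif <- function(t, blood, t_end = Inf) {
  t <- .check_times(t)
  stopifnot(inherits(blood, "blood_params"))
  .infusion_shape(t, blood$c_in, blood$k_out, t_end)
}

#' Blood concentration
#'
#' Concentration of 1H spins in the mixed aqueous phases of whole blood:
#' the arterial input function scaled by the plasma fraction,
#' C_BLOOD(t) = (1 - hct) * AIF(t).
#'
#' @inheritParams aif
#' @return Concentration(s) in mM.
#' @export
blood_concentration <- function(t, blood, t_end = Inf) {
  (1 - blood$hct) * aif(t, blood, t_end)
}

# h(z) = (z e^z - expm1(z)) / z^2 = sum_{m>=2} (m-1)/m! z^(m-2).
# Smooth kernel of the EES closed form; h(0) = 1/2 is the degenerate
# k_ep == k_out limit. Series below |z| = 0.5 avoids the cancellation of
# the direct expression, which loses ~eps/z^2 relative accuracy.
.exp_quad_kernel <- function(z) {
  out <- numeric(length(z))
  small <- abs(z) < 0.5
  if (any(small)) {
    zs <- z[small]
    acc <- rep(0.5, length(zs))
    pow <- rep(1, length(zs))
    mfac <- 2 # m!
    for (m in 3:19) {
      mfac <- mfac * m
      pow <- pow * zs
      acc <- acc + (m - 1) / mfac * pow
    }
    out[small] <- acc
  }
  if (any(!small)) {
    zl <- z[!small]
    out[!small] <- (zl * exp(zl) - expm1(zl)) / zl^2
  }
  out
}

#' EES concentration (Kety-Schmidt exchange with the blood pool)
#'
#' Exact solution of the linear Kety-Schmidt rate equation
#' dC_EES/dt + k_ep * C_EES = k_trans * C_BLOOD(t), C_EES(0) = 0, with
#' C_BLOOD(t) = (1 - hct) * c_in * t * exp(-k_out * t).
#'
#' With A = (1 - hct) * c_in and c = k_ep - k_out the solution is
#' C_EES(t) = k_trans * A * exp(-k_ep t) * \[t e^(ct)/c - (e^(ct) - 1)/c^2\],
#' degenerating to k_trans * A * exp(-k_out t) * t^2 / 2 as c -> 0. Both
#' regimes are evaluated through the single smooth factorization
#' k_trans * A * exp(-k_ep t) * t^2 * h(c t), where h is computed by a
#' power series for small |c t|, so the value is accurate and continuous
#' through the degeneracy.
#'
#' @param t Time(s) in minutes, >= 0; vectorized.
#' @param tissue A [tissue_params] object (uses `k_trans`, `k_ep`).
#' @param blood A [blood_params] object.
#' @return Concentration(s) in mM.
#' @seealso [solve_numeric()] for the independent ODE evaluation.
#' @export
ees_concentration <- function(t, tissue, blood) {
  t <- .check_times(t)
  stopifnot(inherits(tissue, "tissue_params"),
            inherits(blood, "blood_params"))
  A <- (1 - blood$hct) * blood$c_in
  if (tissue$k_trans == 0 || A == 0) return(numeric(length(t)) )
  cc <- tissue$k_ep - blood$k_out
  z <- cc * t
  out <- numeric(length(t))
  small <- abs(z) < 0.5
  if (any(small)) {
    ts <- t[small]
    out[small] <- exp(-tissue$k_ep * ts) * ts^2 * .exp_quad_kernel(z[small])
  }
  if (any(!small)) {
    # algebraically identical form that never multiplies exp(-k_ep t) by
    # exp(+c t): safe for widely separated rates (e.g. quasi-steady k_ep)
    tl <- t[!small]
    out[!small] <- tl * exp(-blood$k_out * tl) / cc -
      (exp(-blood$k_out * tl) - exp(-tissue$k_ep * tl)) / cc^2
  }
  tissue$k_trans * A * out
}

# Distinct-rates closed form for C_IES via partial fractions of
# 1 / ((s+k_out)^2 (s+k_ep) (s+k_ip)): a sum of exp(-k_out t),
# t exp(-k_out t), exp(-k_ep t) and exp(-k_ip t) terms. Requires all
# pairwise gaps among {k_out, k_ep, k_ip} to be resolvable.
.ies_closed <- function(t, tissue, blood) {
  ko <- blood$k_out; ke <- tissue$k_ep; ki <- tissue$k_ip
  A <- (1 - blood$hct) * blood$c_in
  de <- ke - ko; di <- ki - ko; d <- ki - ke
  b  <- 1 / (de^2 * d)
  cc <- -1 / (di^2 * d)
  a2 <- 1 / (de * di)
  a1 <- -(1 / (de^2 * di) + 1 / (de * di^2))
  tissue$k_pi * tissue$k_trans * A *
    (a1 * exp(-ko * t) + a2 * t * exp(-ko * t) +
       b * exp(-ke * t) + cc * exp(-ki * t))
}

.ies_gap_resolvable <- function(t, tissue, blood) {
  gaps <- abs(c(tissue$k_ep - blood$k_out,
                tissue$k_ip - blood$k_out,
                tissue$k_ip - tissue$k_ep))
  min(gaps) * max(max(t), 1) > 0.02
}

#' IES concentration (exchange with the EES)
#'
#' Solution of dC_IES/dt + k_ip * C_IES = k_pi * C_EES(t), C_IES(0) = 0,
#' i.e. the convolution k_pi * integral of C_EES(s) exp(-k_ip (t - s)) ds.
#'
#' The solution is a sum of four exponential modes with rates k_out
#' (doubled), k_ep and k_ip. `method = "auto"` (default) uses the
#' partial-fraction closed form whenever the three rates are pairwise well
#' separated on the time window and falls back to adaptive ODE integration
#' near any coincidence, where the closed-form coefficients become
#' ill-conditioned; `"closed"` and `"ode"` force one path.
#'
#' @inheritParams ees_concentration
#' @param method One of "auto", "closed", "ode".
#' @return Concentration(s) in mM.
#' @export
ies_concentration <- function(t, tissue, blood,
                              method = c("auto", "closed", "ode")) {
  t <- .check_times(t)
  method <- match.arg(method)
  stopifnot(inherits(tissue, "tissue_params"),
            inherits(blood, "blood_params"))
  if (tissue$k_pi == 0 || tissue$k_trans == 0)
    return(numeric(length(t)))
  use_closed <- switch(method,
    closed = TRUE,
    ode = FALSE,
    auto = .ies_gap_resolvable(t, tissue, blood))
  if (use_closed) {
    .ies_closed(t, tissue, blood)
  } else {
    solve_numeric("ies", list(tissue = tissue, blood = blood), t)$values
  }
}

#' Tissue-voxel concentration
#'
#' Signal-producing concentration of a tissue voxel as the volume-weighted
#' mixture of its compartments:
#' C_TISSUE(t) = v_blood C_BLOOD(t) + v_ees C_EES(t) + v_ies C_IES(t).
#' The water-inaccessible compartment (v_now) holds no signal-producing
#' spins and contributes nothing.
#'
#' @inheritParams ies_concentration
#' @return Concentration(s) in mM.
#' @export
tissue_concentration <- function(t, tissue, blood,
                                 method = c("auto", "closed", "ode")) {
  t <- .check_times(t)
  stopifnot(inherits(tissue, "tissue_params"),
            inherits(blood, "blood_params"))
  out <- numeric(length(t))
  if (tissue$v_blood > 0)
    out <- out + tissue$v_blood * blood_concentration(t, blood)
  if (tissue$v_ees > 0)
    out <- out + tissue$v_ees * ees_concentration(t, tissue, blood)
  if (tissue$v_ies > 0)
    out <- out + tissue$v_ies * ies_concentration(t, tissue, blood, method)
  out
}

#' CSF input function
#'
#' Concentration of 1H spins entering a CSF space by blood filtration at
#' rate `k_in_prime` and evacuating it at rate `k_out_prime`, analogous to
#' the arterial input function:
#' CSFIF(t) = k_in_prime * t * exp(-k_out_prime * t). No hematocrit factor
#' is applied to the CSF space itself. An optional infusion end `t_end`
#' continues the curve by pure elimination, as in [aif()].
#'
#' @param t Time(s) in minutes, >= 0; vectorized.
#' @param csf A [csf_params] object.
#' @param t_end End of the infusion window in minutes (default `Inf`).
#' @return Concentration(s) in mM.
#' @export
csf_input_function <- function(t, csf, t_end = Inf) {
  t <- .check_times(t)
  stopifnot(inherits(csf, "csf_params"))
  .infusion_shape(t, csf$k_in_prime, csf$k_out_prime, t_end)
}

#' CSF-voxel concentration
#'
#' Volume-weighted mixture of the two compartments of a CSF voxel:
#' C(t) = v_blood * C_BLOOD(t) + v_csf * CSFIF(t). The mixing rule mirrors
#' the tissue-voxel mixture for the two compartments of a CSF voxel.
#'
#' @inheritParams csf_input_function
#' @param blood A [blood_params] object for the blood compartment.
#' @return Concentration(s) in mM.
#' @export
csf_voxel_concentration <- function(t, csf, blood) {
  t <- .check_times(t)
  stopifnot(inherits(csf, "csf_params"),
            inherits(blood, "blood_params"))
  csf$v_blood * blood_concentration(t, blood) +
    csf$v_csf * csf_input_function(t, csf)
}

#' Numerical ODE evaluation of the tissue models
#'
#' Integrates the coupled EES/IES rate equations with an adaptive
#' high-order solver (deSolve's lsoda) driven by the analytic blood
#' forcing. This is the independent oracle against which the closed-form
#' evaluators are validated, and the fallback path of
#' [ies_concentration()] near rate coincidences.
#'
#' @param model_id One of "ees", "ies", "tissue".
#' @param params A list with elements `tissue` ([tissue_params]) and
#'   `blood` ([blood_params]).
#' @param time_grid Times in minutes (>= 0, strictly increasing after
#'   sorting); the returned curve is sampled at exactly these times.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param t_end Optional end of the infusion window passed to the blood
#'   forcing (default `Inf`).
#' @return A [concentration_curve] over `time_grid`.
#' @export
solve_numeric <- function(model_id, params, time_grid,
                          rtol = 1e-10, atol = 1e-16, t_end = Inf) {
  model_id <- match.arg(model_id, c("ees", "ies", "tissue"))
  tissue <- params$tissue
  blood <- params$blood
  stopifnot(inherits(tissue, "tissue_params"),
            inherits(blood, "blood_params"))
  tg <- .check_times(time_grid)
  if (length(tg) > 1L && any(diff(tg) <= 0))
    stop("'time_grid' must be strictly increasing")
  if (max(tg) == 0) # nothing has entered any compartment yet
    return(concentration_curve(tg, numeric(length(tg))))
  times <- tg
  prepend <- times[1L] > 0
  if (prepend) times <- c(0, times)
  A <- (1 - blood$hct) * blood$c_in
  rhs <- function(t, y, p) {
    cb <- .infusion_shape(t, A, blood$k_out, t_end)
    list(c(tissue$k_trans * cb - tissue$k_ep * y[1L],
           tissue$k_pi * y[1L] - tissue$k_ip * y[2L]))
  }
  sol <- deSolve::ode(y = c(ees = 0, ies = 0), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol, maxsteps = 100000L)
  istate <- attr(sol, "istate")
  if (!is.null(istate) && istate[1L] < 0)
    stop(sprintf("ODE solver failed (istate = %d) for model '%s'",
                 istate[1L], model_id))
  if (prepend) sol <- sol[-1L, , drop = FALSE]
  vals <- switch(model_id,
    ees = sol[, "ees"],
    ies = sol[, "ies"],
    tissue = tissue$v_blood * blood_concentration(tg, blood, t_end) +
      tissue$v_ees * sol[, "ees"] + tissue$v_ies * sol[, "ies"])
  concentration_curve(tg, unname(vals))
}
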