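.check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower))
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower))
  if (x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper))
  as.numeric(x)
}

#' Blood-pool kinetic parameters
#'
#' Parameters of the slow-infusion arterial input function
#' AIF(t) = c_in * t * exp(-k_out * t) and of the blood concentration
#' C_BLOOD(t) = (1 - hct) * AIF(t), where `hct` is the hematocrit.
#'
#' @param c_in Overall input concentration rate in the blood pool, mM/min
#'   (>= 0).
#' @param k_out Overall output (elimination) rate from the blood pool,
#'   1/min (> 0).
#' @param hct Hematocrit, dimensionless fraction in \[0, 1\].
#' @return An object of class `blood_params`.
#' @examples
#' blood_params(c_in = 0.05, k_out = 0.03, hct = 0.45)
#' @export
blood_params <- function(c_in, k_out, hct = 0.45) {
  structure(list(
    c_in  = .check_scalar(c_in, "c_in", lower = 0),
    k_out = .check_scalar(k_out, "k_out", lower = 0, strict_lower = TRUE),
    hct   = .check_scalar(hct, "hct", lower = 0, upper = 1)
  ), class = "blood_params")
}

#' Tissue-voxel kinetic parameters
#'
#' A white/gray-matter voxel is partitioned into four compartments: blood,
#' the extracellular extravascular space (EES), the intracellular
#' extravascular space (IES) and a space not accessible to water 1H spins
#' (NOW). Exchange across the blood-EES barrier happens at rates `k_trans`
#' (in) and `k_ep` (back), across the EES-IES barrier at `k_pi` (in) and
#' `k_ip` (back). The fractional volumes must close to one.
#'
#' @param k_trans Blood to EES transfer rate, 1/min (>= 0). Zero means an
#'   intact blood-brain barrier.
#' @param k_ep EES to blood return rate, 1/min (>= 0).
#' @param k_pi EES to IES transfer rate, 1/min (>= 0).
#' @param k_ip IES to EES return rate, 1/min (>= 0).
#' @param v_blood,v_ees,v_ies Fractional volumes in \[0, 1\].
#' @param v_now Fractional volume of the water-inaccessible space. If
#'   `NULL` (default) it is computed as the remainder
#'   `1 - v_blood - v_ees - v_ies`; if supplied, the four volumes must sum
#'   to 1 within 1e-12.
#' @return An object of class `tissue_params`.
#' @examples
#' tissue_params(k_trans = 5e-4, k_ep = 0.01, k_pi = 0.002, k_ip = 0.005,
#'               v_blood = 0.05, v_ees = 0.20, v_ies = 0.72)
#' @export
tissue_params <- function(k_trans, k_ep, k_pi, k_ip,
                          v_blood, v_ees, v_ies, v_now = NULL) {
  p <- list(
    k_trans = .check_scalar(k_trans, "k_trans", lower = 0),
    k_ep    = .check_scalar(k_ep, "k_ep", lower = 0),
    k_pi    = .check_scalar(k_pi, "k_pi", lower = 0),
    k_ip    = .check_scalar(k_ip, "k_ip", lower = 0),
    v_blood = .check_scalar(v_blood, "v_blood", lower = 0, upper = 1),
    v_ees   = .check_scalar(v_ees, "v_ees", lower = 0, upper = 1),
    v_ies   = .check_scalar(v_ies, "v_ies", lower = 0, upper = 1)
  )
  if (is.null(v_now)) {
    v_now <- 1 - p$v_blood - p$v_ees - p$v_ies
    if (v_now < -1e-12)
      stop("v_blood + v_ees + v_ies exceeds 1; no room for v_now")
    v_now <- max(v_now, 0)
  }
  p$v_now <- .check_scalar(v_now, "v_now", lower = 0, upper = 1)
  closure <- p$v_blood + p$v_ees + p$v_ies + p$v_now
  if (abs(closure - 1) > 1e-12)
    stop(sprintf("fractional volumes must sum to 1 (got %.15g)", closure))
  structure(p, class = "tissue_params")
}

#' CSF-voxel kinetic parameters
#'
#' A CSF voxel holds two compartments, blood and CSF, with fractional
#' volumes closing to one. Water 1H spins filtrate from blood into the CSF
#' space at an overall rate `k_in_prime` and evacuate it at `k_out_prime`;
#' the CSF input function is CSFIF(t) = k_in_prime * t * exp(-k_out_prime * t).
#'
#' @param k_in_prime Overall CSF input rate, mM/min (>= 0).
#' @param k_out_prime Overall CSF output rate, 1/min (> 0).
#' @param v_blood Fractional blood volume in \[0, 1\].
#' @param v_csf Fractional CSF volume; defaults to `1 - v_blood`. If
#'   supplied, `v_blood + v_csf` must equal 1 within 1e-12.
#' @return An object of class `csf_params`.
#' @examples
#' csf_params(k_in_prime = 0.06, k_out_prime = 0.03, v_blood = 0.15)
#' @export
csf_params <- function(k_in_prime, k_out_prime, v_blood = 0, v_csf = NULL) {
  p <- list(
    k_in_prime  = .check_scalar(k_in_prime, "k_in_prime", lower = 0),
    k_out_prime = .check_scalar(k_out_prime, "k_out_prime",
                                lower = 0, strict_lower = TRUE),
    v_blood     = .check_scalar(v_blood, "v_blood", lower = 0, upper = 1)
  )
  if (is.null(v_csf)) v_csf <- 1 - p$v_blood
  p$v_csf <- .check_scalar(v_csf, "v_csf", lower = 0, upper = 1)
  if (abs(p$v_blood + p$v_csf - 1) > 1e-12)
    stop("v_blood + v_csf must equal 1")
  structure(p, class = "csf_params")
}

#' @export
print.blood_params <- function(x, ...) {
  cat(sprintf("<blood_params: c_in=%g mM/min, k_out=%g 1/min, hct=%g>\n",
              x$c_in, x$k_out, x$hct))
  invisible(x)
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf(
    "<tissue_params: k_trans=%g, k_ep=%g, k_pi=%g, k_ip=%g 1/min;\n  volumes blood=%g, ees=%g, ies=%g, now=%g>\n",
    x$k_trans, x$k_ep, x$k_pi, x$k_ip,
    x$v_blood, x$v_ees, x$v_ies, x$v_now))
  invisible(x)
}

#' @export
print.csf_params <- function(x, ...) {
  cat(sprintf(
    "<csf_params: k_in_prime=%g mM/min, k_out_prime=%g 1/min, v_blood=%g, v_csf=%g>\n",
    x$k_in_prime, x$k_out_prime, x$v_blood, x$v_csf))
  invisible(x)
}
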