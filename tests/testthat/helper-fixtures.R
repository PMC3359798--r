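# Shared fixtures: the canonical parameter sets used across the suite,
# plus frozen high-precision oracle values (extended-precision arithmetic
# for the algebraic expressions; lsoda at rtol 1e-13 for the ODE values).

b_ref <- blood_params(c_in = 0.05, k_out = 0.03, hct = 0.45)
# distinct blood elimination rate so the CSF-voxel fit is well posed
b_csf <- blood_params(c_in = 0.05, k_out = 0.035, hct = 0.45)

tissue_ref <- tissue_params(k_trans = 5e-4, k_ep = 0.01,
                            k_pi = 0.002, k_ip = 0.005,
                            v_blood = 0.05, v_ees = 0.20, v_ies = 0.72)
csf_ref <- csf_params(k_in_prime = 0.06, k_out_prime = 0.03,
                      v_blood = 0.15)

grid60 <- seq(0, 60, by = 1)

oracle <- list(
  aif_10     = 0.37040911034085894,   # 0.5 * exp(-0.3)
  blood_10   = 0.20372501068747242,   # 0.55 * aif_10
  csfif_10   = 0.44449093240903070,   # 0.6 * exp(-0.3)
  csfmix_10  = 0.40837604415079698,   # 0.15*blood_10 + 0.85*csfif_10
  blood_30   = 0.33541996928599427,   # 0.825 * exp(-0.9)
  ees_30     = 0.0031042950502010963, # lsoda, rtol 1e-13
  ies_30     = 7.1339412454842377e-05 # lsoda, rtol 1e-13
)

# maximum relative deviation between two sampled curves, normalized by
# the larger curve's sup-norm (robust near zeros)
rel_err <- function(x, y) {
  scale <- max(abs(y))
  if (scale == 0) return(max(abs(x)))
  max(abs(x - y)) / scale
}

# random tissue/blood parameter draw spanning the reported physiological
# ranges; optionally forces a near-degenerate k_ep ~ k_out pair
draw_params <- function(degenerate = FALSE) {
  b <- blood_params(c_in = runif(1, 0.0427, 0.0956),
                    k_out = runif(1, 0.0281, 0.0344),
                    hct = 0.45)
  k_ep <- if (degenerate) b$k_out + runif(1, -1e-6, 1e-6)
          else runif(1, 1e-3, 0.1)
  v_blood <- runif(1, 0.005, 0.08)
  tp <- tissue_params(k_trans = runif(1, 1e-5, 5e-4),
                      k_ep = k_ep,
                      k_pi = runif(1, 1e-4, 5e-3),
                      k_ip = runif(1, 1e-3, 5e-2),
                      v_blood = v_blood,
                      v_ees = 0.20,
                      v_ies = runif(1, 0.60, 0.79 - v_blood))
  list(blood = b, tissue = tp)
}
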