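# Independent oracles used across the suite. These deliberately avoid
# the package's vectorized/ledger code paths: each is a direct scalar
# transcription of the governing equations or a lower-order reference
# scheme.

# term-by-term scalar tally of the nine biological tendency equations
# (umol/L in, umol/L/d out); gamma_t applies to all but the nitrifiers
oracle_tendencies <- function(s, I, Tc, p) {
  gt <- p$temperature$tau *
    exp(p$temperature$a_e * (1 / (Tc + 273.15) - 1 / p$temperature$t0))
  mu_aoo <- p$aoo$y * p$aoo$traits$vmax * s$nh4 / (s$nh4 + p$aoo$traits$k)
  mu_noo <- p$noo$y * p$noo$traits$vmax * s$no2 / (s$no2 + p$noo$traits$k)
  mu_het <- p$het$y_d * p$het$vmax_d * s$det / (s$det + p$het$k_d) * gt

  t1 <- s$nh4 / (s$nh4 + p$phyto$k_nh4p)
  t2 <- s$no2 / (s$no2 + p$phyto$k_no2p)
  t3 <- s$no3 / (s$no3 + p$phyto$k_no3p)
  gn <- t1 + t2 + t3
  gamma <- p$phyto$phi * p$phyto$a_chl * (I * 86400 / 1e6) * 12000
  cap <- p$phyto$mu_max * gn * gt
  theta <- if (cap > 0) p$phyto$theta_max / (1 + gamma * p$phyto$theta_max / (2 * cap))
           else p$phyto$theta_max
  mu_p <- if (cap > 0 && gamma > 0) cap * (1 - exp(-gamma * theta / cap)) else 0
  v1 <- if (gn > 0) mu_p * t1 / gn else 0
  v2 <- if (gn > 0) mu_p * t2 / gn else 0
  v3 <- if (gn > 0) mu_p * t3 / gn else 0

  prey <- s$p + s$b_het + s$b_aoo + s$b_noo
  g <- p$grazing$g_max * gt / (prey + p$grazing$k_g)
  zeta <- p$grazing$zeta
  m_z <- p$grazing$m_z * gt
  m_b <- p$m_b

  list(
    nh4 = -mu_aoo * s$b_aoo / p$aoo$y - mu_noo * s$b_noo - v1 * s$p +
      (1 / p$het$y_d - 1) * mu_het * s$b_het + (1 - zeta) * g * s$z * prey,
    no2 = (1 / p$aoo$y - 1) * mu_aoo * s$b_aoo -
      mu_noo * s$b_noo / p$noo$y - v2 * s$p,
    no3 = mu_noo * s$b_noo / p$noo$y - v3 * s$p,
    det = -mu_het * s$b_het / p$het$y_d +
      m_b * prey + m_z * s$z^2,
    b_het = s$b_het * (mu_het - m_b - g * s$z),
    b_aoo = s$b_aoo * (mu_aoo - m_b - g * s$z),
    b_noo = s$b_noo * (mu_noo - m_b - g * s$z),
    p = s$p * (mu_p - m_b - g * s$z),
    z = zeta * g * s$z * prey - m_z * s$z^2
  )
}

# first-order upwind sinking tendency (reference for the QUICK scheme)
oracle_upwind_sinking <- function(det, w_s, grid) {
  n <- grid$n
  face <- numeric(n + 1)
  face[2:n] <- det[1:(n - 1)]
  flux <- w_s * face
  flux[n + 1] <- 0
  -(flux[2:(n + 1)] - flux[1:n]) / grid$dz
}

# random smooth non-negative column state for cross-checks
random_state <- function(grid, seed = 1) {
  set.seed(seed)
  n <- grid$n
  smooth <- function(scale) {
    x <- stats::filter(stats::runif(n + 20), rep(1 / 10, 10), sides = 1)
    umol_l_to_mol_m3(scale * abs(x[10 + seq_len(n)]) + 1e-6)
  }
  S <- cbind(nh4 = smooth(0.05), no2 = smooth(0.2), no3 = smooth(20),
             det = smooth(0.1), b_het = smooth(0.02), b_aoo = smooth(0.02),
             b_noo = smooth(0.01), p = smooth(0.05), z = smooth(0.03))
  S
}
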