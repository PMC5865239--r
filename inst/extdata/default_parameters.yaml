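# Default biological and physical parameters of the nitricline column
# model. "printed" marks values taken verbatim from primary
# literature; "calibrated" marks defaults chosen to reproduce the
# qualitative structure of a stratified oligotrophic column (see the
# methods vignette). Concentrations in umol N/L, rates per day unless
# noted. Display values are rounded; ecosystem_params() and
# physics_params() hold the authoritative defaults.
stoichiometry:
  f: 0.03              # printed; electron fraction to synthesis
  d: 20                # printed; electron equivalents of C5H7O2N
  d_sd: 4              # printed; from C:N = 5 +/- 1, only C varying
aoo:
  vmax: 50.8           # printed; mol NH4+/mol biomass N/d at 30 C
  vmax_sd: 4.68        # printed; scaled from the O2-uptake s.d.
  k_nm: 133            # printed; half-saturation, nmol/L
  k_sd_nm: 38          # printed
  quota_fmol: 0.12     # printed; 10.2 fg protein/cell at 16% N
noo:
  volume_factor: 10    # printed headline case (1-20 in the ensemble)
  quota_fmol: 1.2      # printed; tenfold AOO protein content
  # vmax, K derived from the AOO by the cube root of volume_factor
het:
  vmax_d: 0.714        # calibrated; y_d*vmax_d = 0.1/d bulk rate (printed)
  k_d: 0.03            # calibrated
  y_d: 0.14            # printed; open-ocean bacterial growth efficiency
phyto:
  mu_max: 0.698        # allometric defaults at 0.6 um diameter (calibrated
  k_nh4p: 0.0039       # anchors: affinity of order 100 L/umol N/d);
  k_no2p: 0.0079       # k_nh4p = 0.5*k_nox by assumption (printed)
  k_no3p: 0.0079
  phi: 0.03            # calibrated; mol C per mol photons
  a_chl: 0.02          # calibrated; m^2 per mg Chl
  theta_max: 0.25      # calibrated; g Chl per g C
  cn_ratio: 6.6        # Redfield C:N
grazing:
  g_max: 1             # printed (order of magnitude, = K_g)
  k_g: 1               # printed
  zeta: 0.5            # printed; grazer N growth efficiency
  m_z: 1               # calibrated; quadratic mortality, per (umol/L)/d
m_b: 0.01              # calibrated; linear microbial mortality
temperature:
  tau: 0.8             # calibrated; Arrhenius normalization
  a_e: -4000           # calibrated; Kelvin (negative: warmer is faster)
  t0: 293.15           # calibrated; reference temperature, K
nitrifier_temperature_exempt: true   # printed: nitrifiers unmodified
physics:
  k_max: 1.0e-2        # calibrated; mixed-layer diffusivity, m^2/s
  k_min: 1.0e-5        # calibrated; interior diffusivity, m^2/s
  z_mld: 20            # calibrated; mixed-layer decay scale, m
  k_w: 0.04            # calibrated; water attenuation, 1/m
  k_chl: 0.02          # calibrated; chlorophyll attenuation, m^2/mg Chl
  i_max: 1400          # calibrated; peak surface irradiance, uEin/m^2/s
  w_s: 10              # calibrated; detritus sinking, m/d
grid:
  H: 2000              # printed; domain height, m
  dz: 5                # printed; vertical resolution, m
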