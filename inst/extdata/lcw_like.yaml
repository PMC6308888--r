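# Emulated woodland-salamander survey: 40 plots x 4 autumn visits.
# Link-scale effects act on standardized covariates; intercepts back-transform
# to occupancy ~0.74, conditional capture ~0.36 (declining with time of day),
# per-transect abundance ~5.8 (density ~0.06 / m2), availability 0.16 for the
# occupancy/abundance species; the paired-species block conditions a
# restricted species (B) on a ubiquitous one (A, psi 0.95) with detection
# rising with coarse woody debris, and independent co-occurrence
# (psi_BA = psi_Ba = 0.72, so phi = 1).
name: lcw_like
n_sites: 40
n_visits: 4
occupancy:
  state:
    "(Intercept)": 1.046
  detection:
    "(Intercept)": -0.575
    TOD: -0.42
nmixture:
  state:
    "(Intercept)": 1.751
  detection:
    "(Intercept)": -0.575
    TOD: -0.43
  availability: 0.16
cooccurrence:
  psi_A: 0.95
  psi_BA: 0.72
  psi_Ba: 0.72
  p_A:
    "(Intercept)": -1.153
    CWD: 0.74
  p_B:
    "(Intercept)": -0.575
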