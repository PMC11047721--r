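# Default montane-stream scenario: 18 transects spanning 485-2865 m with
# three empty transects, 19 species in a mixed turnover/nested regime, and
# a water-temperature column rank-correlated with elevation at |rho| 0.81.
n_sites: 18
n_species: 19
elevation_range: [485.0, 2865.0]
regime: mixed
niche_breadth: 200
occupancy_noise: 0.05
env_elev_rho: 0.81
n_empty_sites: 3
arc_km: 30
neutral_occupancy: 0.4
seed: 101
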