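# Example simulation configuration (all keys optional; defaults apply).
# Energies in kT, time in minutes, volumes in um^3.
kappa: 0.05
alpha_epi: 0.5
alpha_pre: 1.0
phi_pre_ecm: 3.5
epsilon: 2.0
dt: 0.1
growth_rate: 2.5
seed: 1
n_cells: 30
pre_fraction: 0.6
duration_min: 480
record_every_min: 60
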