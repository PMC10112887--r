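# Reduced-scale active monolayer configuration (see ?run_config for keys).
nx: 78
ny: 78
nz: 24
n_cells: 36
R0: 6.0
lambda: 2.0
omega_cw: 0.0025
Omega: 0.4
alpha: 0.1
J: 0.2
Dr: 0.005
dt: 0.25
n_steps: 2000
n_relax: 100
snapshot_every: 50
jitter: 1.0
l_dir: 6.0
l_stress: 2.0
seed: 1
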