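# Reference parameterisation (all values also the package defaults).
# Keys mirror the model parameter names; see ?loadConfig.
h_d: 0.2
h_p: 0.8
p0: 0.256
h_r: 0.93
D_d: 1.0e-5
beta: 1.25
gamma: 4.242
delta: 6.68
mu: 500
pi: 0.5
domain_cm: 0.3
dx_um: 10
dt_hours: 0.044
sigma_mean: 0.016
sigma_min: 0.008
p_T: 0.0042
p_A: 0.042
n_CI: 2
schedule: intermittent
tau_T: 50
tau_H: 20
horizon: 590
seed: 1
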