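# network_params() overrides, flat key/value (keys = argument names)
n_e: 10000
n_i: 2000
g_ie: 0.0027
g_ei: 0.018
theta_epsp: 5
w_in_i: 0.5
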