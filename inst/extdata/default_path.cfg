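# Default early-stage path configuration.
# PLACEHOLDER values: the ellipse coefficients and the seven code maxima are
# configuration, not published constants. Calibrate against an encoded
# reference corpus (see estimate_maxima) before production use.
schema = es-config/1
center_phi = -40
center_psi = 0
axis_a = 110
axis_b = 70
rotation = 0
origin_t = 0
n_samples = 3600
maxima.A = 0.03
maxima.B = 0.17
maxima.C = 0.31
maxima.D = 0.45
maxima.E = 0.60
maxima.F = 0.74
maxima.G = 0.88
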