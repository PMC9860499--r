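# Frozen composition profiles for the synthetic class generators.
# Produced once by scripts/tune_compositions.R (see that file for the
# calibration targets); do not edit by hand.
.CLASS_PROFILES <- list(
  psid = list(
    profile = c(A = 0.060437, R = 0.047746, N = 0.076554, D = 0.037368, C = 0.004133, Q = 0.091078, E = 0.043206, G = 0.138338, H = 0.014724, I = 0.018068, L = 0.030744, K = 0.047224, M = 0.017842, F = 0.026096, P = 0.078826, S = 0.140448, T = 0.047053, W = 0.005429, Y = 0.048111, V = 0.026576),
    concentration = 19.54,
    lengthRange = c(30L, 277L)),
  id = list(
    profile = c(A = 0.023974, R = 0.042475, N = 0.032064, D = 0.094003, C = 0.006987, Q = 0.047689, E = 0.067184, G = 0.199222, H = 0.066190, I = 0.042067, L = 0.052604, K = 0.105462, M = 0.028731, F = 0.014022, P = 0.018378, S = 0.043686, T = 0.084223, W = 0.001240, Y = 0.014952, V = 0.014846),
    concentration = 28.27,
    lengthRange = c(50L, 190L)),
  folded = list(
    profile = c(A = 0.098298, R = 0.054970, N = 0.041184, D = 0.048414, C = 0.012854, Q = 0.039379, E = 0.069629, G = 0.057762, H = 0.017905, I = 0.052661, L = 0.092104, K = 0.054253, M = 0.020975, F = 0.039708, P = 0.059281, S = 0.072918, T = 0.048665, W = 0.012464, Y = 0.028452, V = 0.078123),
    concentration = 277.87,
    lengthRange = c(142L, 258L)))
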