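# Default two-population threshold-linear network.
# Values chosen to reproduce the qualitative signatures (context-dependent
# sign switch of the sound response, preferred-stimulus bimodal boosting);
# they are NOT fitted to data. I = inhibitory (putative L1 interneurons),
# E = excitatory (L2/3 pyramidal cells).
populations: [I, E]
b:                       # context baselines (input units)
  dark:  {I: 1.0, E: 0.0}    # I sits at its activation threshold in the dark
  light: {I: -1.0, E: 0.0}   # light pushes I well below threshold
g_auditory: {I: 1.0, E: 0.6}
g_visual:   {I: -1.0, E: 2.8}  # visual input inhibits I, drives E
G:                       # G[i][j] = weight from j onto i
  I: {I: 0.0, E: 0.0}
  E: {I: -1.5, E: 0.0}   # I inhibits E
nonlin:
  I: {theta: 1.0, k_lo: 0.1, k_hi: 3.0, offset: 0.5}
  E: {theta: 2.0, k_lo: 0.2, k_hi: 2.0, offset: 0.4}
dt: 0.01                 # s
tau_auditory: 0.3        # s, decay of the auditory onset transient
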