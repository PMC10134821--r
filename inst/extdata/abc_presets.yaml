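# Named rejection-ABC preset configurations.
#
# The observed statistics are experimental inputs: the mean and standard
# deviation of the log10 same-well / membrane-separated yield ratio at 48 h
# measured for the lysine-isoleucine auxotroph pair on the 0.1-um membrane.
# They are configuration, not quantities the package recomputes.

equal:
  # Shared leakage stoichiometry for both strains.
  statistic_mode: mean
  t_statistic: 48
  k: 2                       # accept within k * sd of the observed mean
  observed:
    mean: 1.14               # measured mean log10 yield ratio
    sd: 0.235                # measured standard deviation
  priors:
    - name: d                # membrane diffusion rate, L/h
      kind: log_uniform      # one decade centred on the measured mean
      low: 1.22696373214533e-05  # 10^(log10(3.88e-5) - 0.5)
      high: 1.22696373214533e-04 # 10^(log10(3.88e-5) + 0.5)
    - name: e_leak           # leakage stoichiometry, mmol/gDW
      kind: log_uniform      # three decades
      low: 1.0e-02
      high: 10.0

unequal:
  # Independent lysine and isoleucine leakage; diffusion fixed at the
  # measured mean amino-acid rate.
  statistic_mode: per_strain
  t_statistic: 48
  k: 10
  observed:
    mean: {dLys: 0.925, dIle: 1.35}
    sd: {dLys: 0.015, dIle: 0.026}
  priors:
    - name: d
      kind: point
      value: 3.88e-05
    - name: e_lys            # lysine leaked by the isoleucine auxotroph
      kind: log_uniform
      low: 1.0e-02
      high: 10.0
    - name: e_ile            # isoleucine leaked by the lysine auxotroph
      kind: log_uniform
      low: 1.0e-02
      high: 10.0

noisy:
  # As `equal`, with every literature-estimated kinetic parameter (all but
  # the volumes) given a one-decade log-uniform prior around its default.
  statistic_mode: mean
  t_statistic: 48
  k: 2
  observed:
    mean: 1.14
    sd: 0.235
  priors:
    - name: d
      kind: log_uniform
      low: 1.22696373214533e-05
      high: 1.22696373214533e-04
    - name: e_leak
      kind: log_uniform
      low: 1.0e-02
      high: 10.0
    - name: vmax_glc         # mmol/(gDW h), default 10
      kind: log_uniform
      low: 3.16227766016838
      high: 31.6227766016838
    - name: km_glc           # mmol/L, default 0.05
      kind: log_uniform
      low: 0.0158113883008419
      high: 0.158113883008419
    - name: vmax_aa          # mmol/(gDW h), default 1
      kind: log_uniform
      low: 0.316227766016838
      high: 3.16227766016838
    - name: km_aa            # mmol/L, default 0.01
      kind: log_uniform
      low: 3.16227766016838e-03
      high: 3.16227766016838e-02
    - name: y_glc            # gDW/mmol, default 0.09
      kind: log_uniform
      low: 0.0284604989415154
      high: 0.284604989415154
    - name: y_aa_dLys        # gDW/mmol lysine, default 1.5329
      kind: log_uniform
      low: 0.484736918133592
      high: 4.84736918133592
    - name: y_aa_dIle        # gDW/mmol isoleucine, default 2.2482
      kind: log_uniform
      low: 0.710947479929269
      high: 7.10947479929269
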