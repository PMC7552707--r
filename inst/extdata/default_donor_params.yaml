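# Default virtual-donor parameter distribution for the synthetic expansion
# study. Means are calibrated so the six benchmark feeding strategies give
# endpoint cumulative lactate of roughly 10-16 mM-equivalent and harvests of
# roughly 1-2.4e5 cells, with full daily replacement growing the most cells
# and minimal (10%) replacement the fewest. CVs are log-normal
# donor-to-donor coefficients of variation chosen to match the printed
# between-donor spread of the benchmark harvest table.
means:
  mu_max: 0.10        # 1/h, max specific growth rate (unconstrained)
  Ks: 2.0             # mM-eq, substrate-proxy half saturation (growth)
  q_lac: 0.13         # mM per 1e5 cells per h, specific lactate production
  K_inhib: 3.0        # mM, lactate growth-inhibition constant
  death_max: 0.08     # 1/h, specific death rate at full starvation
  X0: 12500           # seeded cells (3300 cells/cm2 x 3.8 cm2)
  Xmax: 320000        # confluence cap, cells
  baseline_S: 5.0     # mM-eq, substrate proxy in fresh medium
  baseline_L: 1.0     # mM, lactate in fresh medium
  working_volume: 1.0 # mL
cv:
  mu_max: 0.05
  Ks: 0.10
  q_lac: 0.12
  K_inhib: 0.10
  death_max: 0.10
  Xmax: 0.08
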