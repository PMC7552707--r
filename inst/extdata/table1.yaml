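# Benchmark medium replacement strategies: fraction of the 1 mL working
# volume exchanged on culture days 1-4 (exchanges at 24, 48, 72, 96 h).
working_volume_mL: 1.0
conditions:
  - condition: 1
    daily_fractions: [0.10, 0.10, 0.25, 0.45]
    replacement_period_h: 24
    note: increasing steps of 0, 15, 20 percentage points
  - condition: 2
    daily_fractions: [0.125, 0.25, 0.365, 0.50]
    replacement_period_h: 24
    note: steady increase of 12.5 percentage points
  - condition: 3
    daily_fractions: [0.10, 0.20, 0.35, 0.45]
    replacement_period_h: 24
    note: decreasing increase of 10, 15, 10 percentage points
  - condition: 4
    daily_fractions: [0.10, 0.10, 0.10, 0.10]
    replacement_period_h: 24
    note: constant minimal replacement
  - condition: 5
    daily_fractions: [0.50, 0.50, 0.50, 0.50]
    replacement_period_h: 24
    note: constant half replacement
  - condition: 6
    daily_fractions: [1.00, 1.00, 1.00, 1.00]
    replacement_period_h: 24
    note: constant full replacement
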