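# Example run configuration: priority worklist with a 6-hour waiting cap.
strategy: prio_maxwait
n_days: 10
t_max: 360
seeds:
  master: 7
operating_point: lowFPR
timing:
  day_mean_arrival_delta: 12
  night_mean_arrival_delta: 45
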