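# Example configuration for the live-cell ATP/Triton experiment:
# intact aequorin-expressing cells, ATP challenge at 30 s, Triton X-100
# lysis at 210 s, recorded through both branches.
experiment: live_cell
atp_fraction: 0.0375
n_total: 2.0e+08
atp_time: 30
triton_time: 210
duration: 450
replicates: 3
det:
  dcr: 904000.0
  pulse_tau: 3.0e-08
qdc:
  gate: 5.0e-06
  sampling_rate: 11200.0
  block: 5600
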