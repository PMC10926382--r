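# Example synthetic scenario: two bait stations triangulating a nest
# 400 m north of BS1. Usable directly with:
#   exec/vespa-simulate --config example-sim.cfg --out-dir demo

[simulation]
stations = BS1:0:0;BS2:300:100
nest_x = 0
nest_y = 400
n_hornets_per_station = 2
trips_per_hornet = 5
speed_mean = 2.7
speed_sd = 0.5
handling_mean = 45
handling_sd = 10
bearing_noise_sd = 3
seed = 1
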