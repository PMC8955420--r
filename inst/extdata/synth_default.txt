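# default simulator configuration: 62-channel montage, 200 Hz, 60-s trials,
# three classes whose gamma-band power on left-hemisphere channels is scaled
# by 0.5 / 1.0 / 2.0 -- the class-conditioned hemispheric asymmetry the
# AsMap pipeline is designed to recover.
montage: seed62
fs: 200
duration_s: 60
noise_power: 1
n_trials_per_class: 5
seed: 1
scheme: seed3
classes: negative neutral positive
power: delta 20
power: theta 10
power: alpha 8
power: beta 4
power: gamma 2
effect: negative gamma 0.5 left
effect: neutral gamma 1.0 left
effect: positive gamma 2.0 left
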