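# canonical EEG frequency bands, inclusive edges in Hz
name: default
band: delta 1 3
band: theta 4 7
band: alpha 8 13
band: beta 14 30
band: gamma 31 50
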