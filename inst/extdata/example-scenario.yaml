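# Reference-activity seminal binary expression drive at reduced scale.
design: sBED
preset: RS
population:
  carrying_capacity: 5000
release:
  males_per_drive: 25
n_reps: 20
horizon: 36
seed: 42
out: sbed-reference
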