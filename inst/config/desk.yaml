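# Desk-scale settings: same conditioning and classifiers, reduced
# simulation size and training budget for interactive runs.
simulation:
  n_pre: 100
  n_post: 100
  duration: 2
cnn:
  epochs: 15
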