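# Reference settings: 10-450 Hz order-4 Butterworth + 60 Hz notch,
# 1000-sample (1000 ms) windows, k = 9, Adam 0.001 / batch 128 / 500 epochs.
preprocessing:
  window_length: 1000
  low_hz: 10
  high_hz: 450
  notch_hz: 60
  notch_q: 30
  test_fraction: 0.2
knn:
  k: 9
cnn:
  learning_rate: 0.001
  batch_size: 128
  epochs: 500
evaluation:
  folds: 5
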