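# Example configuration for the openecho command-line dispatcher.
# Sections map to the corresponding *_config() arguments; unknown keys
# are ignored. This desk-scale example keeps every stage small.
synthdata:
  n_known: 3
  clips_per_class:
    train: 4
    val: 2
    test: 2
  unknown_fraction:
    train: 0.0
    val: 0.5
    test: 0.5
  n_frames: 4
  height: 128
  width: 128
  quality_spread: default
preprocess:
  target_size: 64
  train_frames_per_clip: 4
backbone:
  architecture: small_cnn
  num_classes: 3
train:
  batch_videos: 4
  frames_per_video: 4
  epochs: 2
  lr: 0.001
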