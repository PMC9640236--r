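# One configuration file drives the command-line tools.
model:
  input_side: 64          # pixels, divisible by 32 (full scale: 224)
  num_classes: 3          # RV/Myo/LV; 1 for a single-structure task
  width_multiplier: 0.125 # 1.0 = full VGG19 widths
  num_branches: 2
loss:
  mode: MLDS              # MLDS | DS
  eps_p: 1.0e-7           # BCE probability clamp
  eps_s: 1.0              # Dice smoothing
preprocess:
  k: 5                    # cross-validation folds (case level)
  augment:
    max_translation: 10   # px
    scale_range: [0.9, 1.1]
    rotation_range: [-15, 15]   # degrees
train:
  learning_rate: 2.0e-3   # full-scale protocol: 5.0e-4
  batch_size: 8           # full-scale protocol: 32
  adam_beta1: 0.9
  weight_decay: 1.0e-4
  max_epochs: 40          # full-scale protocol: 1000
  early_stop_patience: 10 # full-scale protocol: 20
  seed: 1
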