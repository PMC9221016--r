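# Augmentation profile for `tilquant.R augment`.
# base: photometric/affine policy (see baseAugmentationPolicy)
# hed:  linear stain-space policy (see sampleHedCoefficients)
base:
  transforms: [flip, rotation, gaussian_noise, gaussian_blur, brightness,
               saturation, contrast]
  prob: 0.5
  params:
    gaussian_noise: [0.0, 8.0]
    brightness: [-26.0, 26.0]
    saturation: [0.8, 1.2]
    contrast: [0.75, 1.25]
hed:
  alphaRange: [0.95, 1.05]
  betaRange: [-0.05, 0.05]
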