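# Desk-scale phantom experiment configuration (the package defaults,
# written out for reference). Any field omitted falls back to the same
# value; see defaultRunConfig().
phantom:
  gridSize: 96
  voxelSpacingMm: 2.0
  atrophyEffect: 0.3
  intensityNoiseSd: 0.08
  misalignRotDegMax: 8.0
  misalignTransMmMax: 8.0
  mtlJitterSd: 0.05
preprocess:
  sliceDirection: posterior-to-anterior
  shrinkFactors: [4, 2]
  maxit: [50, 40]
augment:
  rotationDeg: [-5.0, 5.0]
  scale: [0.95, 1.05]
  translationPx: [-2.0, 2.0]
  contrast: [0.9, 1.1]
  gamma: [0.9, 1.1]
model:
  backbone: tiny_cnn
  featureDim: 64
  inputSize: 32
  cropSize: 48
train:
  batchSize: 64
  baseLr: 0.001
  weightDecay: 5.0e-05
  momentum: 0.9
  lrDecayFactor: 0.1
  maxLrDecays: 3
  plateauTol: 1.0e-04
  plateauPatience: 5
  earlyStopDelta: 5.0e-04
  earlyStopWindow: 5
  maxEpochs: 15
pipeline:
  nAD: 60
  nCN: 60
  useDatasetB: false
  devFraction: 0.8
  k: 5
  nTrials: 3
  seed: 1
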