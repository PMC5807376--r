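# Example pipeline configuration for readRunConfig().
# Scaled-down synthetic cohort with the default planted age effect on mode 2.
seed: 1
r: 9
crossvalThreshold: 15
alpha: 0.05
synthetic:
  nSubjectsPerCell: {young_female: 5, young_male: 5, old_female: 5, old_male: 5}
  duration: 20
  sampleRate: 240
  nMarkers: 37
  nModes: 5
  frequencyJitter: [0.1, 0.1, 0.1, 0.1, 0.1]
  measurementNoiseSD: 0.001
  gapFraction: 0.0
  groupEffects:
    - {group: old, mode: 2, frequency: 0.9, jitter: 1.15}
settings:
  butterworthOrder: 5
  cutoffHz: 7
  firOrder: 50
  passHz: 5
  stopHz: 7
  edgeTrimS: 0.5
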