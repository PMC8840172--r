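# Example pipeline configuration: targets with agronomic cutoffs.
targets:
  - name: yield
    cutoff: 16        # ton/ha
    orientation: high-is-good
  - name: tta
    cutoff: 0.9       # percent citric acid; low acidity is favorable
    orientation: low-is-good
cv_folds: 10
standards_mode: parametric-ci
alpha: 0.01
coverage: 0.90
n_boot: 200
standards_target: yield
gdd:
  Tbase: 7
  TLT: 7
  TUT: 35
chill_threshold: 7.2
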