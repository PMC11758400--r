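# Default pipeline configuration: synthetic case-control cohort matched to
# the published cohort summaries, plus the four screening strategies of the
# five-million-person projection.
seed: 20260101
verbose: false

cohort:
  n_cancer: 617
  n_noncancer: 580
  stage_probs:
    I: 0.263
    II: 0.186
    III: 0.214
    IV: 0.222
    not_staged: 0.053
    missing: 0.062
  feature_auc_targets:
    cna: 0.797
    fs: 0.865
    endmotif: 0.877
    virus: 0.654

model:
  grid_step: 0.05
  poc_cutoff: 0.5
  crs_cutoff: 2.0
  crs_target_specificity: 0.98

projection:
  population: 5000000
  incidence: 0.019
  sens_retrospective_ref: 0.515
  sens_prospective_ref: 0.289
  scenarios:
    - label: OncoSeek
      sensitivity_case_control: 0.499
      specificity: 0.910
      cost_per_test: 80
    - label: SeekInCare
      sensitivity_case_control: 0.600
      specificity: 0.983
      cost_per_test: 750
    - label: Two-step MCED
      sensitivity_case_control: 0.399
      specificity: 0.993
      two_step: OncoSeek
    - label: Galleri
      sensitivity_case_control: 0.515
      specificity: 0.991
      cost_per_test: 949

cost:
  step1_per_test: 80
  step2_per_test: 670
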