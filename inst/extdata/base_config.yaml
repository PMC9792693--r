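# Base-case economic inputs (USD; 1 USD = 6.71 CNY at the study conversion).
# Mirrors default_economics(); load with load_economics().
prices:
  sugemalimab_600mg: 1844.26
  carboplatin_100mg: 13.39
  pemetrexed_100mg: 330.23
  paclitaxel_30mg: 51.39
  docetaxel_20mg: 96.65
per_cycle:
  hospital: 72.43
  followup: 199.55
  bsc: 320.84
sae_cost:
  sugemalimab: 23.57
  placebo: 23.81
sae_prob:
  sugemalimab:
    neutropenia: 0.3250
    nausea_vomiting: 0.0160
    alopecia: 0.0030
    rash: 0.0060
    fatigue: 0.0090
    diarrhoea: 0.0090
  placebo:
    neutropenia: 0.3330
    nausea_vomiting: 0.0250
    fatigue: 0.0060
disutility:
  neutropenia: -0.20
  nausea_vomiting: -0.12
  alopecia: -0.06
  rash: -0.10
  fatigue: -0.07
  diarrhoea: -0.07
utility:
  pfs: 0.804
  pd: 0.321
subsequent:
  sugemalimab:
    docetaxel: 0.531
    crossover: 0.056
    bsc: 0.413
  placebo:
    docetaxel: 0.251
    crossover: 0.277
    bsc: 0.472
dosing:
  bsa_m2: 1.72
  gfr_ml_min: 70
  carboplatin_auc: 5
  pemetrexed_mg_per_m2: 500
  paclitaxel_mg_per_m2: 175
  docetaxel_mg_per_m2: 75
  sugemalimab_mg: 1200
  induction_cycles: 4
  max_treatment_cycles: 35
squamous_fraction: 0.4
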