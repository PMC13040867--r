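# Model 1: perioperative nivolumab + ipilimumab vs adjuvant nivolumab,
# resectable stage III melanoma. US payer perspective, 2025 USD.
# Each entry: base value, low/high sensitivity range, sampling distribution.
# dist families: beta | beta-range (beta rescaled to [low, high]) | gamma |
#                dirichlet (group-normalised, ESS 100 in PSA) |
#                mvn-cholesky (correlated Gompertz shape/rate pair) | fixed
# owsa: fixed  -> held at base in one-way analysis (printed range degenerate)
model_id: 1
settings:
  discount_rate_annual: 0.03
  cycle_length_weeks: 1
  horizon_years: 40
  start_age_years: 62
  wtp: 100000
  gompertz_correlation: -0.5     # shape/rate correlation for PSA sampling
  ade_duration_weeks: 4          # duration over which an ADE disutility applies
  adjuvant_delay_weeks: 6        # surgery -> adjuvant therapy start
  mpf_management_weekly: false   # weekly management in metastatic progression-free
                                 # (false: covered by the per-patient systemic package)
  background_in_metastatic: false # combine background mortality into OS-derived death
  dirichlet_ess: 100
  life_table: life_table_synthetic.csv

clinical:
  braf_mutant_prop:          {base: 0.45, low: 0.39, high: 0.66, dist: beta, units: proportion}
  prnr_braf_mutant:          {base: 0.53, low: 0.42, high: 0.64, dist: beta, units: proportion}
  prnr_braf_wt:              {base: 0.48, low: 0.38, high: 0.57, dist: beta, units: proportion}
  efs_hr_braf_mutant:        {base: 0.29, low: 0.11, high: 0.79, dist: beta-range, units: hazard ratio}
  efs_hr_braf_wt:            {base: 0.35, low: 0.12, high: 1.03, dist: beta-range, units: hazard ratio}
  gomp_shape_adj_nivo_mut:   {base: -0.02525, low: -0.04224, high: -0.00826, dist: mvn-cholesky, pair: adj_nivo_mut, role: shape, units: per week}
  gomp_rate_adj_nivo_mut:    {base: 0.02062, low: 0.01343, high: 0.03166, dist: mvn-cholesky, pair: adj_nivo_mut, role: rate, units: per week}
  gomp_shape_adj_nivo_wt:    {base: -0.01980, low: -0.03796, high: -0.00163, dist: mvn-cholesky, pair: adj_nivo_wt, role: shape, units: per week}
  gomp_rate_adj_nivo_wt:     {base: 0.01373, low: 0.00815, high: 0.02313, dist: mvn-cholesky, pair: adj_nivo_wt, role: rate, units: per week}
  ade_diarrhea_perio_nivoipi: {base: 0.038, low: 0.030, high: 0.046, dist: beta, units: probability}
  ade_rash_perio_nivoipi:     {base: 0.033, low: 0.026, high: 0.040, dist: beta, units: probability}
  ade_diarrhea_adj_nivo:      {base: 0.006, low: 0.005, high: 0.007, dist: beta, units: probability}
  # printed range is degenerate (0.0%-0.0%); held at base in OWSA,
  # beta-sampled on +/-20% bounds in PSA
  ade_rash_adj_nivo:          {base: 0.024, low: 0.0192, high: 0.0288, dist: beta, owsa: fixed, units: probability}
  tp_ef_met_perio_nivoipi_mut: {base: 0.0029, low: 0.00261, high: 0.00319, dist: beta, units: weekly probability}
  tp_ef_met_perio_nivoipi_wt:  {base: 0.0023, low: 0.00207, high: 0.00253, dist: beta, units: weekly probability}
  tp_ef_met_adj_nivo_mut:      {base: 0.0106, low: 0.00954, high: 0.01166, dist: beta, units: weekly probability}
  tp_ef_met_adj_nivo_wt:       {base: 0.0070, low: 0.00630, high: 0.00770, dist: beta, units: weekly probability}
  tp_rem_met:                  {base: 0.01062, low: 0.009558, high: 0.011682, dist: beta, units: weekly probability}
  tp_death_ef:                 {base: 0.00009, low: 0.000081, high: 0.000099, dist: beta, units: weekly probability}
  tp_death_lr:                 {base: 0.00078, low: 0.000702, high: 0.000858, dist: beta, units: weekly probability}
  met_pfs_rate_mut:            {base: 0.00296, low: 0.00269, high: 0.00326, dist: beta, couple: met_mut, units: weekly rate}
  met_os_rate_mut:             {base: 0.00285, low: 0.00257, high: 0.00317, dist: beta, couple: met_mut, units: weekly rate}
  met_pfs_rate_wt:             {base: 0.00414, low: 0.00376, high: 0.00456, dist: beta, couple: met_wt, units: weekly rate}
  met_os_rate_wt:              {base: 0.00237, low: 0.00214, high: 0.00264, dist: beta, couple: met_wt, units: weekly rate}
  hr_pfs_dabtram:              {base: 0.46, low: 0.30, high: 0.72, dist: beta-range, couple: hr_dabtram, units: hazard ratio vs pembrolizumab}
  hr_pfs_nivoipi:              {base: 0.74, low: 0.56, high: 0.98, dist: beta-range, couple: hr_nivoipi, units: hazard ratio vs pembrolizumab}
  hr_os_dabtram:               {base: 1.09, low: 0.68, high: 1.85, dist: beta-range, couple: hr_dabtram, units: hazard ratio vs pembrolizumab}
  hr_os_nivoipi:               {base: 0.79, low: 0.56, high: 1.09, dist: beta-range, couple: hr_nivoipi, units: hazard ratio vs pembrolizumab}
  share_mut_dabtram:           {base: 0.68, low: 0.68, high: 0.68, dist: dirichlet, group: share_mut, units: proportion}
  share_mut_nivoipi:           {base: 0.19, low: 0.19, high: 0.19, dist: dirichlet, group: share_mut, units: proportion}
  share_mut_pembro:            {base: 0.13, low: 0.13, high: 0.13, dist: dirichlet, group: share_mut, units: proportion}
  share_wt_dabtram:            {base: 0.00, low: 0.00, high: 0.00, dist: dirichlet, group: share_wt, units: proportion}
  share_wt_nivoipi:            {base: 0.71, low: 0.71, high: 0.71, dist: dirichlet, group: share_wt, units: proportion}
  share_wt_pembro:             {base: 0.29, low: 0.29, high: 0.29, dist: dirichlet, group: share_wt, units: proportion}

utilities:
  u_event_free:     {base: 0.9130, low: 0.9040, high: 0.9200, dist: beta, units: utility}
  u_lr_recurrence:  {base: 0.8580, low: 0.833, high: 0.884, dist: beta, units: utility}
  # printed base lies outside the printed range; both kept as printed
  u_lr_remission:   {base: 0.8580, low: 0.81, high: 0.846, dist: beta, units: utility}
  u_met_pf:         {base: 0.8280, low: 0.551, high: 0.629, dist: beta, units: utility}
  u_met_prog:       {base: 0.5900, low: 0.395, high: 0.561, dist: beta, units: utility}
  disu_diarrhea:    {base: -0.047, low: -0.056, high: -0.038, dist: beta, units: disutility}
  disu_rash:        {base: -0.033, low: -0.040, high: -0.026, dist: beta, units: disutility}
  disu_vomiting:    {base: -0.048, low: -0.058, high: -0.038, dist: beta, units: disutility}

costs:
  cost_dabrafenib_mg:    {base: 2, low: 2, high: 2, dist: gamma, units: USD per mg}
  cost_trametinib_mg:    {base: 378, low: 303, high: 454, dist: gamma, units: USD per mg}
  cost_nivolumab_mg:     {base: 32, low: 26, high: 39, dist: gamma, units: USD per mg}
  cost_ipilimumab_mg:    {base: 180, low: 144, high: 216, dist: gamma, units: USD per mg}
  cost_pembrolizumab_mg: {base: 58, low: 46, high: 69, dist: gamma, units: USD per mg}
  cost_tvec_mg:          {base: 70, low: 56, high: 84, dist: gamma, units: USD per mg}
  cost_braf_test:        {base: 463, low: 370, high: 555, dist: gamma, units: USD per test}
  mgmt_event_free:       {base: 238, low: 191, high: 286, dist: gamma, units: USD per week}
  mgmt_lr_recurrence:    {base: 261, low: 209, high: 313, dist: gamma, units: USD per week}
  mgmt_lr_remission:     {base: 261, low: 209, high: 313, dist: gamma, units: USD per week}
  mgmt_met_pf:           {base: 1102, low: 881, high: 1322, dist: gamma, units: USD per week}
  mgmt_met_prog:         {base: 1183, low: 947, high: 1420, dist: gamma, units: USD per week}
  cost_surgery:          {base: 11107, low: 8886, high: 13329, dist: gamma, units: USD per procedure}
  cost_systemic_mut:     {base: 556052, low: 444842, high: 667262, dist: gamma, units: USD per patient}
  cost_systemic_wt:      {base: 378411, low: 302729, high: 454093, dist: gamma, units: USD per patient}
  cost_ade_diarrhea:     {base: 8676, low: 6941, high: 10411, dist: gamma, units: USD per event}
  cost_ade_rash:         {base: 3178, low: 2542, high: 3814, dist: gamma, units: USD per event}
  cost_ade_vomiting:     {base: 5294, low: 4235, high: 6353, dist: gamma, units: USD per event}
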