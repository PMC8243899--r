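quantity,value
mean_usd_60m_total,135851
mean_usd_60m_medical,87532
mean_usd_60m_long_term_care,48319
mean_usd_60m_inpatient,61925
mean_usd_60m_outpatient,25607
mean_usd_60m_ltc_institutional,27217
mean_usd_60m_ltc_home,21102
mean_usd_12m_total,50731
mean_usd_12m_medical,38054
mean_usd_12m_long_term_care,12677
cohort_n,16084
n_male,7804
n_female,8280
n_zero_ltc_60m,5125
crosstab_medA_hp_ltc_low_persistent,2080
crosstab_medA_hp_ltc_late_rise,862
crosstab_medA_hp_ltc_progressive,903
crosstab_medA_hp_ltc_high_persistent,2199
crosstab_medA_hp_row_total,6044
largest_total_group_pct,45.6
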