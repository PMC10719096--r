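name,value,ci_low,ci_high
err_per_100mGy_all_heme,1.96,1.10,3.12
err_per_100mGy_lymphoid,2.01,1.02,3.42
err_per_100mGy_myeloid_AL,2.02,0.47,4.77
err_per_100mGy_leukemia_excl_CLL,1.66,0.43,3.74
err_per_100mGy_NHL,2.51,1.14,4.73
err_per_100mGy_HL,1.24,0.08,3.28
ear_per_100k_py_per_100mGy,17.7,11.6,24.0
n_cases_all_heme,790,,
n_cases_lymphoid,578,,
n_cases_myeloid_AL,203,,
n_cases_uk,394,,
n_individuals,876771,,
n_examinations,1331896,,
person_years,6863833,,
typical_exam_dose_mGy,8,,
projection_years,12,,
projection_n_examined,10000,,
dose_lag_years,2,,
mean_cumulative_dose_mGy,15.6,,
median_cumulative_dose_mGy,10.7,,
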