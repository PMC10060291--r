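category,sum_meur,fy_sum_meur
hospitalisation_excl_chemo,206.14,145.17
chemo_session,71.84,54.69
home_hospitalisation,14.62,11.09
rehab,18.40,14.65
emergency,0.10,0.05
high_cost_drug,137.17,114.09
temporary_authorised_drug,42.04,4.92
retrocession_drug,163.92,38.15
community_drug,51.76,26.04
lab_test,12.61,6.00
medical_procedure,8.93,4.50
physician_visit,5.82,2.38
other_professional_visit,18.90,8.44
transport,31.51,18.91
medical_device,10.44,4.90
sick_leave_invalidity,21.79,10.10
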