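target,measure,numerator,denominator
t6,excluded_on_drug_treatment_status,15751,58903
t7,received_sct,1910,6413
t8,autologous_among_sct,1866,1910
t9,died_during_followup,2167,6413
t10,single_lot,2554,6413
t11,any_identifiable_lot,6229,6413
t12,bortezomib_based_at_lot1,6026,6229
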