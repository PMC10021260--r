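item,perspective,category,unit,usd
pulse_oximetry,provider,capital,per_device,149.81
batteries,provider,recurrent,per_device,1.01
personnel_intervention,provider,recurrent,per_child,0.59
personnel_control,provider,recurrent,per_child,0.34
training_intervention,provider,recurrent,per_session,13.96
training_control,provider,recurrent,per_session,7.40
oxygen,provider,recurrent,per_m3,0.77
drugs,patient,patient_expense,per_child,1.01
iv_fluids,patient,patient_expense,per_child,0.88
iv_cannula,patient,patient_expense,per_child,0.34
hospital_stay,patient,patient_expense,per_day,1.18
consultation,patient,patient_expense,per_child,0.40
transport,patient,patient_expense,per_km,0.03
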