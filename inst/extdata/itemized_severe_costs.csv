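arm,item,usd
intervention,pulse_oximetry,191
intervention,batteries,1
intervention,training,27
intervention,personnel,135
intervention,oxygen,743
intervention,consultation,59
intervention,drugs_and_supplies,1221
intervention,transport,559
intervention,hospital_stay,873
control,training,3
control,personnel,15
control,oxygen,171
control,consultation,14
control,drugs_and_supplies,181
control,transport,139
control,hospital_stay,89
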