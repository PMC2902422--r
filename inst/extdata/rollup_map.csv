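group,category
hiv_aids,infectious
pulmonary_tb,infectious
pneumonia,infectious
malaria,infectious
meningitis,infectious
diarrheal,infectious
measles,infectious
other_infectious,infectious
maternity_related,maternal_perinatal_nutrition
preterm_perinatal,maternal_perinatal_nutrition
malnutrition,maternal_perinatal_nutrition
noncommunicable,noncommunicable
other_unspecified,noncommunicable
injuries,injuries
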