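source_code,group
hiv_aids,hiv_aids
pulmonary_tb,pulmonary_tb
pneumonia_sepsis,pneumonia
malaria,malaria
meningitis,meningitis
acute_diarrhoea,diarrheal
chronic_diarrhoea,diarrheal
measles,measles
tetanus,other_infectious
pertussis,other_infectious
other_infectious_disease,other_infectious
maternity_related,maternity_related
prematurity,preterm_perinatal
birth_asphyxia,preterm_perinatal
congenital_malformation,preterm_perinatal
other_perinatal,preterm_perinatal
malnutrition,malnutrition
cancer,noncommunicable
heart_disease,noncommunicable
stroke,noncommunicable
copd_asthma,noncommunicable
liver_disease,noncommunicable
kidney_disease,noncommunicable
diabetes,noncommunicable
transport_accident,injuries
other_injury,injuries
other_unspecified_cause,other_unspecified
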