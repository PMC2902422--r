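source_code,group
hiv_aids,hiv_aids
hiv_related_disease,hiv_aids
pulmonary_tb,pulmonary_tb
extrapulmonary_tb,other_infectious
pneumonia,pneumonia
bronchopneumonia,pneumonia
malaria,malaria
meningitis,meningitis
acute_gastroenteritis,diarrheal
dysentery,diarrheal
cholera,diarrheal
persistent_diarrhoea,diarrheal
measles,measles
typhoid,other_infectious
rabies,other_infectious
tetanus,other_infectious
pertussis,other_infectious
viral_hepatitis,other_infectious
septicaemia,other_infectious
urinary_tract_infection,other_infectious
skin_infection,other_infectious
other_infectious_disease,other_infectious
eclampsia,maternity_related
antepartum_haemorrhage,maternity_related
postpartum_haemorrhage,maternity_related
obstructed_labour,maternity_related
puerperal_sepsis,maternity_related
abortion_related,maternity_related
other_maternal_cause,maternity_related
prematurity,preterm_perinatal
birth_asphyxia,preterm_perinatal
neonatal_sepsis,preterm_perinatal
neonatal_jaundice,preterm_perinatal
birth_injury,preterm_perinatal
congenital_malformation,preterm_perinatal
other_perinatal_cause,preterm_perinatal
marasmus,malnutrition
kwashiorkor,malnutrition
other_malnutrition,malnutrition
cancer_of_cervix,noncommunicable
cancer_of_liver,noncommunicable
cancer_of_oesophagus,noncommunicable
other_cancer,noncommunicable
diabetes_mellitus,noncommunicable
hypertensive_disease,noncommunicable
ischaemic_heart_disease,noncommunicable
cardiac_failure,noncommunicable
stroke,noncommunicable
copd,noncommunicable
asthma,noncommunicable
epilepsy,noncommunicable
liver_cirrhosis,noncommunicable
kidney_disease,noncommunicable
peptic_ulcer_disease,noncommunicable
sickle_cell_disease,noncommunicable
road_traffic_accident,injuries
assault,injuries
suicide,injuries
other_accidental_injury,injuries
senility_or_unspecified,other_unspecified
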