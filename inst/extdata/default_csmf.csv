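cause,probability
hiv_aids,0.210
pulmonary_tb,0.072
pneumonia_sepsis,0.110
malaria,0.030
meningitis,0.020
acute_diarrhoea,0.050
chronic_diarrhoea,0.020
measles,0.010
tetanus,0.005
pertussis,0.005
other_infectious_disease,0.048
maternity_related,0.015
prematurity,0.025
birth_asphyxia,0.012
congenital_malformation,0.005
other_perinatal,0.008
malnutrition,0.020
cancer,0.030
heart_disease,0.040
stroke,0.020
copd_asthma,0.015
liver_disease,0.012
kidney_disease,0.012
diabetes,0.011
transport_accident,0.060
other_injury,0.080
other_unspecified_cause,0.055
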