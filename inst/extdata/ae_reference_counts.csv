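ae_id,n_glp1_class,pct_glp1_class,n_semaglutide,pct_semaglutide,n_ozempic,pct_ozempic,n_wegovy,pct_wegovy,n_mounjaro,pct_mounjaro,n_tirzepatide,pct_tirzepatide,n_zepbound,pct_zepbound
gastrointestinal_general,210,4.30,95,0.55,488,2.61,296,3.47,241,5.98,19,0.45,16,0.90
nausea,158,3.23,197,1.15,317,1.69,175,2.05,86,2.13,48,1.14,23,1.30
vomiting,113,2.31,99,0.58,308,1.64,228,2.67,153,3.80,17,0.40,11,0.62
pancreatitis,139,2.85,52,0.30,165,0.88,91,1.07,44,1.09,12,0.29,7,0.40
constipation,59,1.21,64,0.37,143,0.76,82,0.96,38,0.94,26,0.62,16,0.90
diarrhea,64,1.31,59,0.34,155,0.83,83,0.97,36,0.89,19,0.45,12,0.68
abdominal_pain,51,1.04,22,0.13,112,0.60,34,0.40,19,0.47,6,0.14,2,0.11
gallbladder_issues,13,0.27,4,0.02,61,0.33,36,0.42,3,0.07,1,0.02,1,0.06
indigestion,2,0.04,5,0.03,6,0.03,0,0.00,5,0.12,0,0.00,0,0.00
loss_of_appetite,4,0.08,2,0.01,5,0.03,4,0.05,0,0.00,0,0.00,0,0.00
gerd,5,0.10,2,0.01,4,0.02,1,0.01,1,0.02,0,0.00,0,0.00
liver_damage,0,0.00,1,0.01,1,0.01,0,0.00,0,0.00,0,0.00,0,0.00
jaundice,0,0.00,1,0.01,0,0.00,0,0.00,0,0.00,0,0.00,0,0.00
depression,42,0.86,151,0.88,165,0.88,134,1.57,19,0.47,13,0.40,9,0.62
anxiety,39,0.80,59,0.34,70,0.37,36,0.42,19,0.47,13,0.31,9,0.51
mood_swings,3,0.06,24,0.14,15,0.08,14,0.16,2,0.05,3,0.07,0,0.00
insomnia,4,0.08,7,0.04,6,0.03,1,0.01,5,0.12,2,0.05,0,0.00
restlessness,1,0.02,0,0.00,0,0.00,0,0.00,0,0.00,0,0.00,0,0.00
hair_loss,48,0.98,50,0.29,153,0.82,77,0.90,80,1.98,15,0.36,17,0.96
rash,8,0.16,51,0.30,25,0.13,5,0.06,6,0.15,4,0.10,1,0.06
fever,2,0.04,5,0.03,7,0.04,5,0.06,3,0.07,1,0.02,2,0.11
sweating,3,0.06,9,0.05,13,0.07,4,0.05,2,0.05,1,0.02,0,0.00
allergies,1,0.02,14,0.08,7,0.04,3,0.04,2,0.05,1,0.02,0,0.00
hives,6,0.12,1,0.01,7,0.04,1,0.01,1,0.02,1,0.02,0,0.00
sore_throat,2,0.04,0,0.00,3,0.02,3,0.04,0,0.00,0,0.00,0,0.00
dry_mouth,0,0.00,1,0.01,0,0.00,0,0.00,0,0.00,1,0.02,0,0.00
headache,21,0.43,111,0.65,22,0.12,13,0.15,7,0.17,78,1.86,3,0.17
joint_pain,10,0.20,97,0.57,4,0.02,2,0.02,4,0.10,71,1.69,1,0.06
dizziness,8,0.16,15,0.09,19,0.10,16,0.19,2,0.05,0,0.00,1,0.06
muscle_weakness,2,0.04,2,0.01,2,0.01,2,0.02,2,0.05,1,0.02,0,0.00
back_pain,0,0.00,7,0.04,1,0.01,0,0.00,2,0.05,0,0.00,0,0.00
seizures,0,0.00,4,0.02,6,0.03,0,0.00,0,0.00,0,0.00,0,0.00
muscle_cramps,0,0.00,3,0.02,0,0.00,0,0.00,0,0.00,0,0.00,0,0.00
tingling_sensation,0,0.00,1,0.01,0,0.00,0,0.00,0,0.00,0,0.00,0,0.00
fatigue,29,0.59,111,0.65,65,0.35,47,0.55,21,0.52,33,0.79,18,1.02
vision_changes,4,0.08,3,0.02,4,0.02,3,0.04,3,0.07,2,0.05,2,0.11
dehydration,4,0.08,12,0.07,8,0.04,3,0.04,2,0.05,0,0.00,0,0.00
hypertension,32,0.66,53,0.31,24,0.13,25,0.29,11,0.27,21,0.50,13,0.73
persistent_cough,0,0.00,0,0.00,22,0.12,0,0.00,22,0.55,0,0.00,0,0.00
swelling,1,0.02,24,0.14,10,0.05,7,0.08,2,0.05,4,0.10,0,0.00
copd,4,0.08,0,0.00,7,0.04,0,0.00,1,0.02,0,0.00,0,0.00
blood_clots,4,0.08,2,0.01,2,0.01,1,0.01,1,0.02,1,0.02,0,0.00
increased_heart_rate,0,0.00,2,0.01,2,0.01,3,0.04,1,0.02,1,0.02,0,0.00
heart_palpitations,0,0.00,3,0.02,2,0.01,0,0.00,2,0.05,1,0.02,0,0.00
shortness_of_breath,0,0.00,1,0.01,0,0.00,4,0.05,0,0.00,0,0.00,0,0.00
hypoglycemia,29,0.59,31,0.18,80,0.43,33,0.39,9,0.22,7,0.17,2,0.11
thyroid_tumor,8,0.16,15,0.09,54,0.29,20,0.23,9,0.22,3,0.07,1,0.06
erectile_dysfunction,1,0.02,10,0.06,2,0.01,2,0.02,0,0.00,5,0.12,0,0.00
kidney_damage,4,0.08,4,0.02,5,0.03,1,0.01,2,0.05,1,0.02,0,0.00
elevated_blood_sugar,0,0.00,0,0.00,1,0.01,0,0.00,0,0.00,0,0.00,0,0.00
irregular_menstrual_cycle,0,0.00,0,0.00,1,0.01,0,0.00,0,0.00,0,0.00,0,0.00
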