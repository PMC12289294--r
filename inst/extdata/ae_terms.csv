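ae_id,ae_category,surface_form
gastrointestinal_general,gastrointestinal,gastrointestinal
gastrointestinal_general,gastrointestinal,gi issues
gastrointestinal_general,gastrointestinal,gi problems
gastrointestinal_general,gastrointestinal,gi distress
gastrointestinal_general,gastrointestinal,stomach issues
nausea,gastrointestinal,nausea
vomiting,gastrointestinal,vomiting
diarrhea,gastrointestinal,diarrhea
constipation,gastrointestinal,constipation
abdominal_pain,gastrointestinal,abdominal pain
abdominal_pain,gastrointestinal,stomach pain
loss_of_appetite,gastrointestinal,loss of appetite
loss_of_appetite,gastrointestinal,appetite loss
indigestion,gastrointestinal,indigestion
jaundice,gastrointestinal,jaundice
pancreatitis,gastrointestinal,pancreatitis
gallbladder_issues,gastrointestinal,gallbladder issues
gallbladder_issues,gastrointestinal,gallbladder problems
gallbladder_issues,gastrointestinal,gallbladder disease
gerd,gastrointestinal,gastroesophageal reflux disease
gerd,gastrointestinal,gerd
gerd,gastrointestinal,acid reflux
liver_damage,gastrointestinal,liver damage
headache,neuromuscular,headache
headache,neuromuscular,headaches
dizziness,neuromuscular,dizziness
seizures,neuromuscular,seizures
seizures,neuromuscular,seizure
muscle_cramps,neuromuscular,muscle cramps
muscle_cramps,neuromuscular,muscle cramp
tingling_sensation,neuromuscular,tingling sensation
tingling_sensation,neuromuscular,tingling
joint_pain,neuromuscular,joint pain
muscle_weakness,neuromuscular,muscle weakness
back_pain,neuromuscular,back pain
persistent_cough,cardiovascular_respiratory,persistent cough
swelling,cardiovascular_respiratory,swelling
increased_heart_rate,cardiovascular_respiratory,increased heart rate
increased_heart_rate,cardiovascular_respiratory,rapid heart rate
shortness_of_breath,cardiovascular_respiratory,shortness of breath
hypertension,cardiovascular_respiratory,hypertension
hypertension,cardiovascular_respiratory,high blood pressure
copd,cardiovascular_respiratory,chronic obstructive pulmonary disease
copd,cardiovascular_respiratory,copd
blood_clots,cardiovascular_respiratory,blood clots
blood_clots,cardiovascular_respiratory,blood clot
heart_palpitations,cardiovascular_respiratory,heart palpitations
heart_palpitations,cardiovascular_respiratory,palpitations
rash,dermatologic_immunologic,rash
sweating,dermatologic_immunologic,sweating
hives,dermatologic_immunologic,hives
sore_throat,dermatologic_immunologic,sore throat
fever,dermatologic_immunologic,fever
dry_mouth,dermatologic_immunologic,dry mouth
hair_loss,dermatologic_immunologic,hair loss
hair_loss,dermatologic_immunologic,losing hair
allergies,dermatologic_immunologic,allergies
allergies,dermatologic_immunologic,allergy
elevated_blood_sugar,endocrine_metabolic,elevated blood sugar levels
elevated_blood_sugar,endocrine_metabolic,elevated blood sugar
elevated_blood_sugar,endocrine_metabolic,high blood sugar
irregular_menstrual_cycle,endocrine_metabolic,irregular menstrual cycle
irregular_menstrual_cycle,endocrine_metabolic,irregular menstrual cycles
irregular_menstrual_cycle,endocrine_metabolic,irregular periods
thyroid_tumor,endocrine_metabolic,thyroid tumor
thyroid_tumor,endocrine_metabolic,thyroid tumors
thyroid_tumor,endocrine_metabolic,thyroid cancer
erectile_dysfunction,endocrine_metabolic,erectile dysfunction
kidney_damage,endocrine_metabolic,kidney damage
kidney_damage,endocrine_metabolic,kidney failure
hypoglycemia,endocrine_metabolic,hypoglycemia
hypoglycemia,endocrine_metabolic,low blood sugar
depression,mental_health_behavioral,depression
anxiety,mental_health_behavioral,anxiety
mood_swings,mental_health_behavioral,mood swings
insomnia,mental_health_behavioral,insomnia
restlessness,mental_health_behavioral,restlessness
vision_changes,general,vision changes
vision_changes,general,blurry vision
fatigue,general,fatigue
dehydration,general,dehydration
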