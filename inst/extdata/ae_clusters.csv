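ae_id,cluster
allergies,1
anxiety,1
depression,1
copd,1
fatigue,1
fever,1
hypertension,1
indigestion,1
insomnia,1
gerd,1
hives,1
swelling,1
restlessness,1
seizures,1
constipation,2
dehydration,2
headache,2
diarrhea,2
dizziness,2
hypoglycemia,2
sweating,2
jaundice,2
gastrointestinal_general,3
nausea,3
vomiting,3
pancreatitis,3
rash,3
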