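pt	soc
Hypotension	Vascular disorders
Hypertension	Vascular disorders
Shock	Vascular disorders
Capillary leak syndrome	Vascular disorders
Tachycardia	Cardiac disorders
Sinus tachycardia	Cardiac disorders
Cardiac arrest	Cardiac disorders
Cardio-respiratory arrest	Cardiac disorders
Heart failure	Cardiac disorders
Pericardial effusion	Cardiac disorders
Mitral valve disease	Cardiac disorders
Mitral valve incompetence	Cardiac disorders
Bradycardia	Cardiac disorders
Cardiomyopathy	Cardiac disorders
Arrhythmia	Cardiac disorders
Cytokine release syndrome	Immune system disorders
Pyrexia	General disorders and administration site conditions
Febrile neutropenia	Blood and lymphatic system disorders
Neutropenia	Blood and lymphatic system disorders
Headache	Nervous system disorders
Seizure	Nervous system disorders
Vomiting	Gastrointestinal disorders
Diarrhoea	Gastrointestinal disorders
Acute kidney injury	Renal and urinary disorders
Hypoxia	Respiratory, thoracic and mediastinal disorders
Fatigue	General disorders and administration site conditions
Sepsis	Infections and infestations
Neurotoxicity	Nervous system disorders
Encephalopathy	Nervous system disorders
Rash	Skin and subcutaneous tissue disorders
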