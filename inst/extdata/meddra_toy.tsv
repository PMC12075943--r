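pt	soc
Injection site pain	General disorders and administration site conditions
Injection site erythema	General disorders and administration site conditions
Injection site pruritus	General disorders and administration site conditions
Injection site reaction	General disorders and administration site conditions
Pyrexia	General disorders and administration site conditions
Malaise	General disorders and administration site conditions
Condition aggravated	General disorders and administration site conditions
Illness	General disorders and administration site conditions
Swelling	General disorders and administration site conditions
Inflammation	General disorders and administration site conditions
Infection	Infections and infestations
Sinusitis	Infections and infestations
Influenza	Infections and infestations
Cellulitis	Infections and infestations
Nasopharyngitis	Infections and infestations
Pneumonia	Infections and infestations
Septic shock	Infections and infestations
Sepsis	Infections and infestations
Measles	Infections and infestations
Necrotising fasciitis streptococcal	Infections and infestations
Intestinal sepsis	Infections and infestations
Urticaria	Skin and subcutaneous tissue disorders
Rash	Skin and subcutaneous tissue disorders
Pruritus	Skin and subcutaneous tissue disorders
Abdominal pain	Gastrointestinal disorders
Nausea	Gastrointestinal disorders
Diarrhoea	Gastrointestinal disorders
Mouth ulceration	Gastrointestinal disorders
Cough	Respiratory, thoracic and mediastinal disorders
Oropharyngeal pain	Respiratory, thoracic and mediastinal disorders
Rhinorrhoea	Respiratory, thoracic and mediastinal disorders
Dyspnoea	Respiratory, thoracic and mediastinal disorders
Pulmonary embolism	Respiratory, thoracic and mediastinal disorders
Arthralgia	Musculoskeletal and connective tissue disorders
Joint swelling	Musculoskeletal and connective tissue disorders
Arthritis	Musculoskeletal and connective tissue disorders
Rheumatoid arthritis	Musculoskeletal and connective tissue disorders
C-reactive protein increased	Investigations
Haemoglobin decreased	Investigations
Contusion	Injury, poisoning and procedural complications
Off label use	Injury, poisoning and procedural complications
Headache	Nervous system disorders
Dizziness	Nervous system disorders
Lymphadenopathy	Blood and lymphatic system disorders
Pancytopenia	Blood and lymphatic system disorders
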