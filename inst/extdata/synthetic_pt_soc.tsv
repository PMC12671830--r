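pt	soc
Injection site pain	General disorders and administration site conditions
Injection site erythema	General disorders and administration site conditions
Pyrexia	General disorders and administration site conditions
Fatigue	General disorders and administration site conditions
Malaise	General disorders and administration site conditions
Drug ineffective	General disorders and administration site conditions
Nasopharyngitis	Infections and infestations
Influenza	Infections and infestations
Sinusitis	Infections and infestations
Clostridium difficile infection	Infections and infestations
Upper respiratory tract infection	Infections and infestations
Abdominal pain	Gastrointestinal disorders
Diarrhoea	Gastrointestinal disorders
Vomiting	Gastrointestinal disorders
Nausea	Gastrointestinal disorders
Haematochezia	Gastrointestinal disorders
Frequent bowel movements	Gastrointestinal disorders
Off-label use	Injury, poisoning and procedural complications
Overdose	Injury, poisoning and procedural complications
Incorrect dose administered	Injury, poisoning and procedural complications
Uveitis	Eye disorders
Conjunctivitis	Eye disorders
Headache	Nervous system disorders
Dizziness	Nervous system disorders
Arthralgia	Musculoskeletal and connective tissue disorders
Back pain	Musculoskeletal and connective tissue disorders
Rash	Skin and subcutaneous tissue disorders
Pruritus	Skin and subcutaneous tissue disorders
Urticaria	Skin and subcutaneous tissue disorders
Device leakage	Product issues
Device malfunction	Product issues
Crohn's disease	Gastrointestinal disorders
Ulcerative colitis	Gastrointestinal disorders
Juvenile idiopathic arthritis	Musculoskeletal and connective tissue disorders
Rheumatoid arthritis	Musculoskeletal and connective tissue disorders
Psoriasis	Skin and subcutaneous tissue disorders
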