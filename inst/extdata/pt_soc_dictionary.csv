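pt,soc
Dyspnoea,"Respiratory, thoracic and mediastinal disorders"
Pneumonia,Infections and infestations
Fluid retention,Metabolism and nutrition disorders
Pulmonary arterial hypertension,"Respiratory, thoracic and mediastinal disorders"
Oedema peripheral,General disorders and administration site conditions
Pulmonary hypertension,"Respiratory, thoracic and mediastinal disorders"
Oedema,General disorders and administration site conditions
Peripheral swelling,General disorders and administration site conditions
Cardiac failure congestive,Cardiac disorders
Syncope,Nervous system disorders
Oxygen saturation decreased,Investigations
Chest pain,General disorders and administration site conditions
Nasal congestion,"Respiratory, thoracic and mediastinal disorders"
Respiratory failure,"Respiratory, thoracic and mediastinal disorders"
Dyspnoea exertional,"Respiratory, thoracic and mediastinal disorders"
Cardiac failure,Cardiac disorders
Right ventricular failure,Cardiac disorders
Hospitalisation,Surgical and medical procedures
Unevaluable event,General disorders and administration site conditions
Pulmonary oedema,"Respiratory, thoracic and mediastinal disorders"
Hypotension,Vascular disorders
Hypoxia,"Respiratory, thoracic and mediastinal disorders"
Chronic obstructive pulmonary disease,"Respiratory, thoracic and mediastinal disorders"
Transfusion,Surgical and medical procedures
Aspartate aminotransferase increased,Investigations
Pain in jaw,Musculoskeletal and connective tissue disorders
Alanine aminotransferase increased,Investigations
Liver function test abnormal,Investigations
Swelling,General disorders and administration site conditions
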