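drug,pt
bosentan,Dyspnoea
ambrisentan,Dyspnoea
macitentan,Dyspnoea
bosentan,Pneumonia
ambrisentan,Pneumonia
macitentan,Pneumonia
bosentan,Fluid retention
ambrisentan,Fluid retention
macitentan,Fluid retention
bosentan,Pulmonary arterial hypertension
ambrisentan,Pulmonary arterial hypertension
macitentan,Pulmonary arterial hypertension
bosentan,Oedema peripheral
ambrisentan,Oedema peripheral
macitentan,Oedema peripheral
bosentan,Pulmonary hypertension
ambrisentan,Pulmonary hypertension
macitentan,Pulmonary hypertension
bosentan,Oedema
ambrisentan,Oedema
macitentan,Oedema
bosentan,Peripheral swelling
ambrisentan,Peripheral swelling
macitentan,Peripheral swelling
bosentan,Cardiac failure congestive
ambrisentan,Cardiac failure congestive
macitentan,Cardiac failure congestive
bosentan,Syncope
ambrisentan,Syncope
macitentan,Syncope
bosentan,Oxygen saturation decreased
bosentan,Chest pain
ambrisentan,Chest pain
macitentan,Chest pain
ambrisentan,Nasal congestion
macitentan,Nasal congestion
bosentan,Respiratory failure
ambrisentan,Respiratory failure
macitentan,Respiratory failure
bosentan,Dyspnoea exertional
ambrisentan,Dyspnoea exertional
macitentan,Dyspnoea exertional
bosentan,Cardiac failure
ambrisentan,Cardiac failure
macitentan,Cardiac failure
bosentan,Right ventricular failure
ambrisentan,Right ventricular failure
macitentan,Right ventricular failure
macitentan,Hospitalisation
ambrisentan,Unevaluable event
bosentan,Pulmonary oedema
ambrisentan,Pulmonary oedema
macitentan,Pulmonary oedema
macitentan,Hypotension
bosentan,Hypoxia
ambrisentan,Hypoxia
macitentan,Hypoxia
bosentan,Chronic obstructive pulmonary disease
ambrisentan,Chronic obstructive pulmonary disease
macitentan,Chronic obstructive pulmonary disease
bosentan,Aspartate aminotransferase increased
bosentan,Alanine aminotransferase increased
bosentan,Liver function test abnormal
ambrisentan,Liver function test abnormal
bosentan,Swelling
ambrisentan,Swelling
macitentan,Swelling
bosentan,Acute respiratory failure
ambrisentan,Acute respiratory failure
macitentan,Acute respiratory failure
bosentan,Catheterisation cardiac
ambrisentan,Catheterisation cardiac
macitentan,Catheterisation cardiac
macitentan,Haemoglobin decreased
bosentan,Blood bilirubin increased
macitentan,Blood bilirubin increased
bosentan,Pericardial effusion
ambrisentan,Pericardial effusion
macitentan,Pericardial effusion
bosentan,Device related infection
ambrisentan,Device related infection
macitentan,Device related infection
bosentan,Haemoptysis
ambrisentan,Haemoptysis
macitentan,Haemoptysis
bosentan,Blood alkaline phosphatase increased
ambrisentan,Palpitations
ambrisentan,Therapy interrupted
bosentan,Atrial fibrillation
bosentan,Ascites
macitentan,Ascites
bosentan,Presyncope
ambrisentan,Presyncope
macitentan,Presyncope
bosentan,Scleroderma
ambrisentan,Scleroderma
macitentan,Scleroderma
macitentan,Pleural effusion
macitentan,Productive cough
bosentan,Oxygen consumption increased
ambrisentan,Oxygen consumption increased
macitentan,Oxygen consumption increased
macitentan,Therapy non-responder
macitentan,Concomitant disease aggravated
ambrisentan,Infusion site pain
macitentan,Infusion site pain
ambrisentan,Intentional dose omission
bosentan,Pulmonary fibrosis
ambrisentan,Pulmonary fibrosis
bosentan,Pulmonary arterial pressure increased
ambrisentan,Pulmonary arterial pressure increased
macitentan,Pulmonary arterial pressure increased
ambrisentan,Therapy change
macitentan,Therapy change
ambrisentan,Sinus congestion
macitentan,Sinus congestion
bosentan,Atrial flutter
macitentan,Atrial flutter
bosentan,Exercise tolerance decreased
ambrisentan,Exercise tolerance decreased
macitentan,Exercise tolerance decreased
bosentan,Hepatic cirrhosis
macitentan,Hepatic cirrhosis
macitentan,Disease complication
bosentan,Generalised oedema
ambrisentan,Generalised oedema
macitentan,Generalised oedema
ambrisentan,Hypervolaemia
macitentan,Hypervolaemia
bosentan,Gamma-glutamyltransferase increased
bosentan,Cardiac failure acute
ambrisentan,Cardiac failure acute
macitentan,Cardiac failure acute
bosentan,Left ventricular failure
ambrisentan,Left ventricular failure
macitentan,Left ventricular failure
ambrisentan,Infusion site erythema
macitentan,Infusion site erythema
ambrisentan,Central venous catheterisation
bosentan,Cor pulmonale
ambrisentan,Cor pulmonale
ambrisentan,Vascular device infection
macitentan,Vascular device infection
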