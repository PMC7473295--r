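condition_id,system,code,role,description
angina,ICD10,I20,diagnosis,Angina pectoris
angina,READ,G33..,event,Angina pectoris
angina,READ,G330.,event,Angina decubitus
angina,READ,G33z.,event,Angina pectoris NOS
heart_attack,ICD10,I21,diagnosis,Acute myocardial infarction
heart_attack,ICD10,I22,diagnosis,Subsequent myocardial infarction
heart_attack,READ,G30..,event,Acute myocardial infarction
heart_attack,READ,G300.,event,Acute anterolateral infarction
heart_attack,READ,G30X.,event,Acute transmural MI unspecified site
heart_failure,ICD10,I50,diagnosis,Heart failure
heart_failure,READ,G58..,event,Heart failure
heart_failure,READ,G580.,event,Congestive heart failure
heart_failure,READ,G581.,event,Left ventricular failure
asthma,ICD10,J45,diagnosis,Asthma
asthma,ICD10,J46,diagnosis,Status asthmaticus
asthma,READ,H33..,event,Asthma
asthma,READ,H330.,event,Extrinsic atopic asthma
asthma,READ,H331.,event,Intrinsic asthma
asthma,READ,H33z.,event,Asthma NOS
asthma,READ,c111.,medication,Salbutamol inhaler (illustrative)
asthma,READ,c112.,medication,Terbutaline inhaler (illustrative)
asthma,READ,c611.,medication,Beclometasone inhaler (illustrative)
asthma,READ,c612.,medication,Budesonide inhaler (illustrative)
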