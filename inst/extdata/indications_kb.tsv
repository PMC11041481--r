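drug	indication
acetaminophen	pain
acetaminophen	fever
senna	constipation
oxycodone	pain
morphine	pain
coumadin	afib
albuterol	wheeze
albuterol	sob
vancomycin	pneumonia
amlodipine	hypertension
metoprolol	hypertension
isosorbide	hypertension
aspirin	stroke
plavix	stroke
lasix	edema
pantoprazole	nausea
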