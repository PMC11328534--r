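patient_id,note_id,llt_code,drug_id,serious
p002,n00005,L010,D08,0
p002,n00006,L015,D08,0
p002,n00008,L032,D01,0
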