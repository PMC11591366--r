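specimen,condyle,flexion,mean_mm,sd_mm
Specimen 1,medial,0deg,2.0,0.4
Specimen 1,lateral,0deg,2.0,0.3
Specimen 1,medial,90deg,1.9,0.3
Specimen 1,lateral,90deg,2.0,0.1
Specimen 2,medial,0deg,2.2,0.3
Specimen 2,lateral,0deg,1.5,0.3
Specimen 2,medial,90deg,1.6,0.1
Specimen 2,lateral,90deg,1.9,0.1
Specimen 3,medial,0deg,1.5,0.4
Specimen 3,lateral,0deg,2.8,0.2
Specimen 3,medial,90deg,1.2,0.3
Specimen 3,lateral,90deg,2.3,0.3
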