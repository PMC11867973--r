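well,row_tag,col_tag,model,drug,moa,concentration,unit,replicate,is_control
A01,R1,C1,JHOS2,drug01,moa01,1000,nM,1,FALSE
A02,R1,C2,JHOS2,drug01,moa01,1000,nM,2,FALSE
A03,R1,C3,JHOS2,drug02,moa02,1000,nM,1,FALSE
A04,R1,C4,JHOS2,drug02,moa02,1000,nM,2,FALSE
A05,R1,C5,JHOS2,drug03,moa03,1000,nM,1,FALSE
A06,R1,C6,JHOS2,drug03,moa03,1000,nM,2,FALSE
A07,R1,C7,JHOS2,drug04,moa04,1000,nM,1,FALSE
A08,R1,C8,JHOS2,drug04,moa04,1000,nM,2,FALSE
A09,R1,C9,JHOS2,drug05,moa05,1000,nM,1,FALSE
A10,R1,C10,JHOS2,drug05,moa05,1000,nM,2,FALSE
A11,R1,C11,JHOS2,drug06,moa06,1000,nM,1,FALSE
A12,R1,C12,JHOS2,drug06,moa06,1000,nM,2,FALSE
B01,R2,C1,JHOS2,drug07,moa07,1000,nM,1,FALSE
B02,R2,C2,JHOS2,drug07,moa07,1000,nM,2,FALSE
B03,R2,C3,JHOS2,drug08,moa08,1000,nM,1,FALSE
B04,R2,C4,JHOS2,drug08,moa08,1000,nM,2,FALSE
B05,R2,C5,JHOS2,drug09,moa09,1000,nM,1,FALSE
B06,R2,C6,JHOS2,drug09,moa09,1000,nM,2,FALSE
B07,R2,C7,JHOS2,drug10,moa10,1000,nM,1,FALSE
B08,R2,C8,JHOS2,drug10,moa10,1000,nM,2,FALSE
B09,R2,C9,JHOS2,drug11,moa11,1000,nM,1,FALSE
B10,R2,C10,JHOS2,drug11,moa11,1000,nM,2,FALSE
B11,R2,C11,JHOS2,drug12,moa12,1000,nM,1,FALSE
B12,R2,C12,JHOS2,drug12,moa12,1000,nM,2,FALSE
C01,R3,C1,JHOS2,drug13,moa13,1000,nM,1,FALSE
C02,R3,C2,JHOS2,drug13,moa13,1000,nM,2,FALSE
C03,R3,C3,JHOS2,drug14,moa01,1000,nM,1,FALSE
C04,R3,C4,JHOS2,drug14,moa01,1000,nM,2,FALSE
C05,R3,C5,JHOS2,drug15,moa02,1000,nM,1,FALSE
C06,R3,C6,JHOS2,drug15,moa02,1000,nM,2,FALSE
C07,R3,C7,JHOS2,drug16,moa03,1000,nM,1,FALSE
C08,R3,C8,JHOS2,drug16,moa03,1000,nM,2,FALSE
C09,R3,C9,JHOS2,drug17,moa04,1000,nM,1,FALSE
C10,R3,C10,JHOS2,drug17,moa04,1000,nM,2,FALSE
C11,R3,C11,JHOS2,drug18,moa05,1000,nM,1,FALSE
C12,R3,C12,JHOS2,drug18,moa05,1000,nM,2,FALSE
D01,R4,C1,JHOS2,drug19,moa06,1000,nM,1,FALSE
D02,R4,C2,JHOS2,drug19,moa06,1000,nM,2,FALSE
D03,R4,C3,JHOS2,drug20,moa07,1000,nM,1,FALSE
D04,R4,C4,JHOS2,drug20,moa07,1000,nM,2,FALSE
D05,R4,C5,JHOS2,drug21,moa08,1000,nM,1,FALSE
D06,R4,C6,JHOS2,drug21,moa08,1000,nM,2,FALSE
D07,R4,C7,JHOS2,drug22,moa09,1000,nM,1,FALSE
D08,R4,C8,JHOS2,drug22,moa09,1000,nM,2,FALSE
D09,R4,C9,JHOS2,drug23,moa10,1000,nM,1,FALSE
D10,R4,C10,JHOS2,drug23,moa10,1000,nM,2,FALSE
D11,R4,C11,JHOS2,drug24,moa11,1000,nM,1,FALSE
D12,R4,C12,JHOS2,drug24,moa11,1000,nM,2,FALSE
E01,R5,C1,JHOS2,drug25,moa12,1000,nM,1,FALSE
E02,R5,C2,JHOS2,drug25,moa12,1000,nM,2,FALSE
E03,R5,C3,JHOS2,drug26,moa13,1000,nM,1,FALSE
E04,R5,C4,JHOS2,drug26,moa13,1000,nM,2,FALSE
E05,R5,C5,JHOS2,drug27,moa01,1000,nM,1,FALSE
E06,R5,C6,JHOS2,drug27,moa01,1000,nM,2,FALSE
E07,R5,C7,JHOS2,drug28,moa02,1000,nM,1,FALSE
E08,R5,C8,JHOS2,drug28,moa02,1000,nM,2,FALSE
E09,R5,C9,JHOS2,drug29,moa03,1000,nM,1,FALSE
E10,R5,C10,JHOS2,drug29,moa03,1000,nM,2,FALSE
E11,R5,C11,JHOS2,drug30,moa04,1000,nM,1,FALSE
E12,R5,C12,JHOS2,drug30,moa04,1000,nM,2,FALSE
F01,R6,C1,JHOS2,drug31,moa05,1000,nM,1,FALSE
F02,R6,C2,JHOS2,drug31,moa05,1000,nM,2,FALSE
F03,R6,C3,JHOS2,drug32,moa06,1000,nM,1,FALSE
F04,R6,C4,JHOS2,drug32,moa06,1000,nM,2,FALSE
F05,R6,C5,JHOS2,drug33,moa07,1000,nM,1,FALSE
F06,R6,C6,JHOS2,drug33,moa07,1000,nM,2,FALSE
F07,R6,C7,JHOS2,drug34,moa08,1000,nM,1,FALSE
F08,R6,C8,JHOS2,drug34,moa08,1000,nM,2,FALSE
F09,R6,C9,JHOS2,drug35,moa09,1000,nM,1,FALSE
F10,R6,C10,JHOS2,drug35,moa09,1000,nM,2,FALSE
F11,R6,C11,JHOS2,drug36,moa10,1000,nM,1,FALSE
F12,R6,C12,JHOS2,drug36,moa10,1000,nM,2,FALSE
G01,R7,C1,JHOS2,drug37,moa11,1000,nM,1,FALSE
G02,R7,C2,JHOS2,drug37,moa11,1000,nM,2,FALSE
G03,R7,C3,JHOS2,drug38,moa12,1000,nM,1,FALSE
G04,R7,C4,JHOS2,drug38,moa12,1000,nM,2,FALSE
G05,R7,C5,JHOS2,drug39,moa13,1000,nM,1,FALSE
G06,R7,C6,JHOS2,drug39,moa13,1000,nM,2,FALSE
G07,R7,C7,JHOS2,drug40,moa01,1000,nM,1,FALSE
G08,R7,C8,JHOS2,drug40,moa01,1000,nM,2,FALSE
G09,R7,C9,JHOS2,drug41,moa02,1000,nM,1,FALSE
G10,R7,C10,JHOS2,drug41,moa02,1000,nM,2,FALSE
G11,R7,C11,JHOS2,drug42,moa03,1000,nM,1,FALSE
G12,R7,C12,JHOS2,drug42,moa03,1000,nM,2,FALSE
H01,R8,C1,JHOS2,drug43,moa04,1000,nM,1,FALSE
H02,R8,C2,JHOS2,drug43,moa04,1000,nM,2,FALSE
H03,R8,C3,JHOS2,drug44,moa05,1000,nM,1,FALSE
H04,R8,C4,JHOS2,drug44,moa05,1000,nM,2,FALSE
H05,R8,C5,JHOS2,drug45,moa06,1000,nM,1,FALSE
H06,R8,C6,JHOS2,drug45,moa06,1000,nM,2,FALSE
H07,R8,C7,JHOS2,DMSO,control,0,nM,1,TRUE
H08,R8,C8,JHOS2,DMSO,control,0,nM,2,TRUE
H09,R8,C9,JHOS2,DMSO,control,0,nM,3,TRUE
H10,R8,C10,JHOS2,DMSO,control,0,nM,4,TRUE
H11,R8,C11,JHOS2,DMSO,control,0,nM,5,TRUE
H12,R8,C12,JHOS2,DMSO,control,0,nM,6,TRUE
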