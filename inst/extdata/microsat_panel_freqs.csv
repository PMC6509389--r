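locus,allele,freq
RP3,80,0.10
RP3,90,0.05
RP3,100,0.03
RP3,110,0.24
RP3,120,0.02
RP3,130,0.20
RP3,140,0.33
RP3,150,0.03
RP3,170,0.00
RP15,85,0.00
RP15,90,0.01
RP15,100,0.08
RP15,105,0.01
RP15,110,0.73
RP15,120,0.17
RP17,90,0.01
RP17,100,0.10
RP17,110,0.35
RP17,120,0.34
RP17,130,0.01
RP17,220,0.03
RP17,240,0.02
RP17,250,0.00
RP17,260,0.04
RP17,270,0.01
RP17,280,0.02
RP17,310,0.01
RP17,360,0.02
RP17,370,0.00
RP17,420,0.01
RP17,430,0.01
RP17,440,0.00
RP17,450,0.01
RP17,460,0.00
RP17,490,0.01
RP17,510,0.00
RP23,40,0.01
RP23,80,0.00
RP23,90,0.04
RP23,100,0.65
RP23,110,0.13
RP23,120,0.06
RP23,130,0.11
SFC128,80,0.00
SFC128,90,0.06
SFC128,100,0.09
SFC128,110,0.08
SFC128,120,0.46
SFC128,130,0.18
SFC128,140,0.11
SFC128,150,0.08
SFC128,160,0.00
SFC128,170,0.00
SFC134,100,0.06
SFC134,110,0.36
SFC134,115,0.01
SFC134,120,0.49
SFC134,130,0.01
SFC134,150,0.00
SFC134,160,0.00
SFC139,70,0.00
SFC139,100,0.01
SFC139,110,0.26
SFC139,120,0.05
SFC139,130,0.06
SFC139,140,0.05
SFC139,150,0.03
SFC139,160,0.10
SFC139,170,0.10
SFC139,180,0.05
SFC139,190,0.05
SFC139,200,0.04
SFC139,210,0.13
SFC139,220,0.02
SFC139,230,0.03
SFC139,240,0.01
SFC139,250,0.00
RP193,90,0.01
RP193,95,0.02
RP193,100,0.02
RP193,110,0.01
RP193,115,0.13
RP193,117,0.03
RP193,120,0.08
RP193,125,0.04
RP193,127,0.03
RP193,130,0.54
RP193,140,0.09
RP193,150,0.01
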