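pig_id,batch,period,diet_id,dmi,gei,geo,geu
diet-mean-d1,1,1,d1,1.356,5867,626,123
diet-mean-d2,1,1,d2,1.384,5986,761,102
diet-mean-d3,1,1,d3,1.214,5291,688,96
diet-mean-d4,1,1,d4,1.292,5470,1247,85
diet-mean-d5,1,1,d5,1.181,5089,301,125
diet-mean-d6,1,1,d6,1.237,5263,415,55
diet-mean-d7,1,1,d7,1.309,5761,859,118
diet-mean-d8,1,1,d8,1.264,5677,838,99
diet-mean-d9,1,1,d9,1.290,5470,875,112
diet-mean-d10,1,1,d10,1.448,6390,601,206
diet-mean-d11,1,1,d11,1.353,5948,597,160
diet-mean-d12,1,1,d12,1.366,6055,632,186
diet-mean-d13,1,1,d13,1.332,5908,631,192
diet-mean-d14,1,1,d14,1.441,6710,713,180
diet-mean-d15,1,1,d15,1.351,5983,581,158
diet-mean-d16,1,1,d16,1.422,6225,995,179
diet-mean-d17,1,1,d17,1.434,6333,949,217
diet-mean-d18,1,1,d18,1.239,5450,988,140
diet-mean-d19,1,1,d19,1.335,5964,1550,137
diet-mean-d20,1,1,d20,1.344,5845,1096,141
diet-mean-v1,1,1,v1,1.410,6245,777,158
diet-mean-v2,1,1,v2,1.358,5962,587,152
diet-mean-v3,1,1,v3,1.289,5679,764,120
diet-mean-v4,1,1,v4,1.383,6168,772,95
diet-mean-v5,1,1,v5,1.299,5682,783,80
diet-mean-v6,1,1,v6,1.288,5742,705,138
diet-mean-v7,1,1,v7,1.299,5683,1201,153
diet-mean-v8,1,1,v8,1.424,6397,1328,201
diet-mean-v9,1,1,v9,1.415,6274,1124,166
diet-mean-v10,1,1,v10,1.415,6452,827,189
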