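diet_id,dm,ge,cp,ash,ndf,adf
d1,88.00,4327,9.20,4.13,8.58,1.95
d2,89.71,4325,14.79,3.61,9.81,2.72
d3,88.09,4358,9.99,3.63,9.25,2.62
d4,89.74,4234,10.43,4.88,18.32,6.49
d5,87.96,4308,13.58,3.76,6.94,0.34
d6,87.79,4253,9.62,4.02,3.15,0.95
d7,88.65,4401,15.44,4.91,15.65,3.97
d8,89.53,4490,10.31,5.86,10.92,3.10
d9,89.31,4239,11.19,6.35,12.20,4.42
d10,88.29,4414,21.64,5.23,10.05,3.54
d11,87.89,4396,22.06,5.30,9.25,3.03
d12,89.81,4432,23.71,5.28,13.33,3.78
d13,89.46,4435,22.86,5.57,10.72,2.41
d14,89.69,4657,16.87,4.91,8.97,3.24
d15,88.62,4430,21.44,5.04,11.80,4.24
d16,88.75,4377,17.35,5.16,11.29,4.62
d17,88.32,4417,17.29,4.89,13.63,6.20
d18,88.88,4397,16.31,5.23,13.13,6.22
d19,89.65,4467,12.78,6.01,23.53,11.96
d20,89.11,4349,11.38,4.89,16.60,4.78
v1,88.09,4428,20.78,5.40,11.84,3.97
v2,88.08,4391,20.42,5.07,8.66,3.10
v3,88.14,4407,20.26,5.18,11.80,4.46
v4,88.14,4460,20.68,5.47,9.68,3.61
v5,88.41,4373,20.95,5.84,12.37,4.59
v6,89.47,4459,21.08,5.45,10.18,3.42
v7,88.69,4376,20.76,5.99,13.99,6.78
v8,88.72,4491,20.81,5.72,18.50,9.37
v9,88.33,4434,20.73,5.40,14.73,6.19
v10,88.90,4561,20.69,5.15,12.12,3.98
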