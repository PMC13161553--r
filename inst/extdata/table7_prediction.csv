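diet_id,quantity,determined,predicted,sem,p_label
v1,de,3872,3841,25.3,0.275
v1,me,3759,3688,33.2,0.086
v2,de,3959,3996,18.6,0.102
v2,me,3841,3846,40.7,0.919
v3,de,3814,3860,19.5,0.076
v3,me,3720,3707,9.2,0.236
v4,de,3900,4004,15.6,0.001
v4,me,3830,3854,18.7,0.256
v5,de,3770,3792,13.9,0.181
v5,me,3700,3639,25.3,0.061
v6,de,3914,4000,17.5,0.004
v6,me,3801,3850,22.1,0.077
v7,de,3450,3633,6.3,<0.001
v7,me,3331,3478,13.0,<0.001
v8,de,3554,3616,24.4,0.053
v8,me,3417,3460,19.3,0.077
v9,de,3640,3682,19.1,0.093
v9,me,3523,3527,22.4,0.880
v10,de,3976,3980,10.1,0.702
v10,me,3842,3830,11.3,0.376
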