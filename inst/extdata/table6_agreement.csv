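diet_id,quantity,determined,calculated
v1,ge,4428,4410
v1,ivde,3643,3660
v1,de,3872,3879
v1,me,3759,3738
v2,ge,4391,4374
v2,ivde,3817,3815
v2,de,3959,3961
v2,me,3841,3839
v3,ge,4407,4383
v3,ivde,3670,3679
v3,de,3814,3839
v3,me,3720,3709
v4,ge,4460,4447
v4,ivde,3823,3823
v4,de,3900,3952
v4,me,3830,3829
v5,ge,4373,4356
v5,ivde,3606,3612
v5,de,3770,3795
v5,me,3700,3667
v6,ge,4459,4460
v6,ivde,3823,3819
v6,de,3914,3940
v6,me,3801,3821
v7,ge,4376,4371
v7,ivde,3453,3453
v7,de,3450,3467
v7,me,3331,3335
v8,ge,4491,4484
v8,ivde,3422,3435
v8,de,3554,3567
v8,me,3417,3417
v9,ge,4434,4421
v9,ivde,3504,3501
v9,de,3640,3658
v9,me,3523,3507
v10,ge,4561,4531
v10,ivde,3801,3800
v10,de,3976,3967
v10,me,3842,3833
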