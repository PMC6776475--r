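age_years,sex,bmi_lower,bmi_upper
3,Boys,14.4,17.7
3,Girls,14.2,17.6
4,Boys,14.2,17.6
4,Girls,14.0,17.3
5,Boys,14.1,17.4
5,Girls,13.9,17.1
6,Boys,14.0,17.6
6,Girls,13.9,17.3
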