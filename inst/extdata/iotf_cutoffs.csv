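age_months,sex,overweight,obesity
48,male,17.55,19.29
48,female,17.28,19.15
84,male,17.92,20.63
84,female,17.75,20.51
120,male,19.84,24.00
120,female,19.86,24.11
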