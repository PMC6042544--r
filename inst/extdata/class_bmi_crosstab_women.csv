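class,lt18.5,b18.5_24.9,b25.0_29.9,b30.0_34.9,ge35.0
I,1215,33371,1725,0,0
II,3,12584,28636,4607,2
III,83,1683,4777,10587,6414
IV,14,382,519,614,2369
V,12,253,368,437,848
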