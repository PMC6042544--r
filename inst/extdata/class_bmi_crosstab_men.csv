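class,lt18.5,b18.5_24.9,b25.0_29.9,b30.0_34.9,ge35.0
I,312,50171,68646,1736,1
II,319,1860,14097,23472,4635
III,47,859,3335,1943,539
IV,172,437,679,917,2558
V,25,139,210,166,178
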