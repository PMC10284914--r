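COG0012
COG0016
COG0052
COG0080
COG0081
COG0087
COG0091
COG0093
COG0096
COG0098
COG0100
COG0124
COG0185
COG0197
COG0200
COG0215
COG0256
COG0495
COG0541
COG0552
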