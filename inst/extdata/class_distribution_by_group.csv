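class,control,standardized
1,33,11
2,23,28
3,31,81
4,36,79
5,33,90
6,30,83
7,21,21
8,17,6
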