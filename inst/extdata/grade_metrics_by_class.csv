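class,accuracy,precision,recall,f1
2,96.1,96.0784314,100,98
3,94.6,98.1481481,96.3636364,97.2477064
4,93.9,97.2972973,96.4285714,96.8609865
5,90.2,94.0677966,95.6896552,94.8717949
6,92,97.1962617,94.5454545,95.8525346
7,92.9,97.5,95.1219512,96.2962963
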