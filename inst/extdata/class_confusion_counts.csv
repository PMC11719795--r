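class,tp,fp,fn,total,accuracy,precision,recall,f1
1,43,1,0,44,97.727,97.72727273,100,98.8505747
2,47,3,1,51,92.2,94,97.91666667,95.9183673
3,106,2,4,112,94.6,98.14814815,96.36363636,97.2477064
4,108,2,5,115,93.9,98.18181818,95.57522124,96.8609865
5,113,1,9,123,91.9,99.12280702,92.62295082,95.7627119
6,113,0,0,113,100.0,100,100,100
7,37,3,2,42,88.1,92.5,94.87179487,93.6708861
8,23,0,0,23,100.0,100,100,100
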