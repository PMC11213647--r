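patient,me_hu,sd_hu,mae_hu
1,-0.8,94.7,37.6
2,-3.3,102.9,40.5
3,0.5,84.3,36.1
4,-5.8,79.2,33.4
5,-5.7,87.5,37.2
6,-4.5,88.3,35.9
7,-1.4,95.4,40.6
8,-5.1,86.0,35.0
9,-2.6,89.0,40.1
10,-1.0,81.0,35.0
11,1.3,84.5,35.0
12,-4.6,79.2,35.6
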