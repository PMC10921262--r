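"seed","dose","package_version","dt_ms"
1,4.4,"0.1.0",0.05
2,1.60666666666667,"0.1.0",0.05
3,4.44,"0.1.0",0.05
4,2.32,"0.1.0",0.05
5,2.81333333333333,"0.1.0",0.05
6,4.18666666666667,"0.1.0",0.05
7,3.1,"0.1.0",0.05
8,4.75333333333333,"0.1.0",0.05
9,3,"0.1.0",0.05
10,4.64,"0.1.0",0.05
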