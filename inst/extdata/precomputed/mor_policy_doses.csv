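"seed","policy","dose","silent_control","silent_opioid","tonic_control","tonic_opioid","package_version","dt_ms"
1,"random",4.4,57.9166666666667,79.5833333333333,37.0833333333333,17.0833333333333,"0.1.0",0.05
1,"low_gleak",4,57.9166666666667,98.3333333333333,37.0833333333333,0,"0.1.0",0.05
1,"high_gleak",1.76,57.9166666666667,57.9166666666667,37.0833333333333,37.0833333333333,"0.1.0",0.05
2,"random",1.60666666666667,57.0833333333333,77.9166666666667,36.6666666666667,19.1666666666667,"0.1.0",0.05
2,"low_gleak",4.76,57.0833333333333,97.5,36.6666666666667,0,"0.1.0",0.05
2,"high_gleak",0.68,57.0833333333333,57.0833333333333,36.6666666666667,36.6666666666667,"0.1.0",0.05
3,"random",4.44,60,82.0833333333333,32.9166666666667,14.1666666666667,"0.1.0",0.05
3,"low_gleak",5.16,60,97.9166666666667,32.9166666666667,0,"0.1.0",0.05
3,"high_gleak",1.48,60,60.4166666666667,32.9166666666667,32.9166666666667,"0.1.0",0.05
4,"random",2.32,51.25,75.4166666666667,42.0833333333333,20,"0.1.0",0.05
4,"low_gleak",4.96,51.25,97.9166666666667,42.0833333333333,0,"0.1.0",0.05
4,"high_gleak",1.22,51.25,51.6666666666667,42.0833333333333,42.0833333333333,"0.1.0",0.05
5,"random",2.81333333333333,57.5,76.6666666666667,36.6666666666667,20.4166666666667,"0.1.0",0.05
5,"low_gleak",4.12,57.5,97.9166666666667,36.6666666666667,0,"0.1.0",0.05
5,"high_gleak",1.2,57.5,57.5,36.6666666666667,36.6666666666667,"0.1.0",0.05
6,"random",4.18666666666667,57.5,80.8333333333333,34.1666666666667,16.6666666666667,"0.1.0",0.05
6,"low_gleak",4,57.5,98.3333333333333,34.1666666666667,0,"0.1.0",0.05
6,"high_gleak",2.64,57.5,57.9166666666667,34.1666666666667,34.1666666666667,"0.1.0",0.05
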