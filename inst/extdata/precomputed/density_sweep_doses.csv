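"seed","factor","density_pct","total_strength","dose","package_version","dt_ms"
1,1,1.00334448160535,2673,4.4,"0.1.0",0.05
1,4,4.0133779264214,2625.75,4.28,"0.1.0",0.05
2,1,1.00334448160535,2781,1.60666666666667,"0.1.0",0.05
2,4,4.0133779264214,2718.75,4.28,"0.1.0",0.05
3,1,1.00334448160535,2727,4.44,"0.1.0",0.05
3,4,4.0133779264214,2721,4.4,"0.1.0",0.05
4,1,1.00334448160535,2643,2.32,"0.1.0",0.05
4,4,4.0133779264214,2661.75,4.56,"0.1.0",0.05
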