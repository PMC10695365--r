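measure,group,subject,term1,term2
isolation,Hippo,,0.760,0.720
isolation,Okapi,,0.000,0.000
isolation,Panda,,0.447,0.589
proximity,Hippo,A3,0.910,0.710
proximity,Hippo,C4,0.876,0.799
proximity,Hippo,B5,0.000,0.363
proximity,Hippo,B6,0.240,0.000
proximity,Okapi,A4,0.496,0.822
proximity,Okapi,C5,0.690,0.690
proximity,Okapi,C1,0.755,0.774
proximity,Okapi,C2,0.000,0.000
proximity,Panda,A1,0.000,0.780
proximity,Panda,B7,0.000,0.204
proximity,Panda,B1,0.000,0.484
proximity,Panda,B2,0.000,0.000
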