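item,PC1,PC2,PC3,PC4,PC5
NO center area entry,0.401,0.288,0.107,-0.086,-0.162
NO distance,0.413,0.265,0.092,-0.107,0.138
NO head entry,0.376,0.341,-0.037,-0.167,-0.111
EPM open area entry,-0.279,0.416,0.093,0.045,-0.323
EPM close area entry,-0.389,0.307,0.186,-0.133,-0.108
EPM distance,-0.337,0.382,0.201,-0.128,-0.040
OF distance,-0.042,0.322,-0.561,0.063,-0.011
OF center area entry,0.080,0.232,-0.492,0.418,0.265
GL handling,-0.026,0.126,0.134,0.731,-0.310
GL avoid,0.134,-0.012,-0.358,-0.335,-0.577
GL approach,-0.276,0.079,-0.247,-0.301,0.287
TC distance,-0.066,-0.369,-0.185,0.026,-0.493
TC animal area entry,0.278,0.032,0.310,0.040,-0.007
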