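run,Dry extract ratio,Albiflorin,Paeoniflorin,Liquiritin,Glycyrrhizic acid,Ganoderic acid A
1,13.93,1.35,5.19,0.42,1.28,0.09
2,21.62,0.86,4.89,0.47,0.93,0.08
3,22.74,1.11,5.02,0.44,1.19,0.09
4,16.32,0.95,4.75,0.45,1.04,0.09
5,20.39,1.11,5.07,0.35,0.92,0.08
6,21.83,0.99,5.22,0.38,0.89,0.05
7,18.61,1.20,5.30,0.38,1.36,0.14
8,17.88,1.09,5.42,0.35,1.21,0.12
9,22.95,0.90,4.76,0.44,1.39,0.16
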