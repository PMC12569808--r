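criterion,subjective,objective,combined
Albiflorin,31.85,17.17,33.23
Paeoniflorin,31.85,9.64,18.66
Liquiritin,12.91,36.01,28.26
Glycyrrhizic acid,12.91,17.18,13.48
Ganoderic acid A,5.24,10.33,3.29
Dry extract ratio,5.24,9.68,3.08
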