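label,context,v1,v2,v3
Albiflorin,batch,1.25,1.28,1.24
Paeoniflorin,batch,5.44,5.37,5.46
Liquiritin,batch,0.42,0.44,0.43
Glycyrrhizic acid,batch,1.28,1.31,1.32
Ganoderic acid A,batch,0.14,0.15,0.14
Dry extract ratio,batch,18.63,17.86,18.21
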