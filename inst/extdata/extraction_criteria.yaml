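# Quality criteria for the extraction orthogonal experiment.
# tier: importance rank (1 = most important); two criteria per tier.
# tier_ratio_map: judgment-matrix ratio by tier gap (1 within a tier,
# 3 one tier apart, 5 two tiers apart).
criteria:
  - {name: "Albiflorin", tier: 1, direction: benefit}
  - {name: "Paeoniflorin", tier: 1, direction: benefit}
  - {name: "Liquiritin", tier: 2, direction: benefit}
  - {name: "Glycyrrhizic acid", tier: 2, direction: benefit}
  - {name: "Ganoderic acid A", tier: 3, direction: benefit}
  - {name: "Dry extract ratio", tier: 3, direction: benefit}
tier_ratio_map: {0: 1, 1: 3, 2: 5}
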