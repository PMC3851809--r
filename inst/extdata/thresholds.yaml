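# Default diagnostic thresholds for small intervention groups.
# comparators: eq   -- flag when observed != value
#              gt   -- flag when observed <= value
#              lt   -- flag when observed >= value
#              band -- flag when observed <= lower or >= upper
metrics:
  isolates:
    comparator: eq
    value: 0
  degree_min:
    comparator: gt
    value: 1
  reciprocity_nonnull:
    comparator: gt
    value: 0.50
  excess_components:
    comparator: eq
    value: 0
  density:
    comparator: band
    lower: 0.15
    upper: 0.50
  centralization:
    comparator: lt
    value: 0.25
  transitivity_pct:
    comparator: gt
    value: 0.3
  cohesion_compactness:
    comparator: gt
    value: 0.25
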