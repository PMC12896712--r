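# Desk-scale run: three populations, reduced genome (2,000 markers,
# 100 QTL) and herd sizes; completes in minutes.
scale: desk
populations: [A, B, C]
fst_threshold: 0.1
fractions: [0.10, 0.15, 0.20]
aggregate: centroid
models: [gblup, ssgblup, wgblup]
varcomp: "true"
replicates: 2
master_seed: 1
baseline: true
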