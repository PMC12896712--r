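# Full-scale run mirroring the complete study design: 50k markers,
# 725 QTL, 1095 historical generations, ~2000-dam herds, 100 selected
# generations, five replicates. Runs for many hours on one CPU and is
# shipped for completeness; it has not been exercised end to end at this
# scale.
scale: full
populations: [A, B, C]
fst_threshold: 0.1
fractions: [0.10, 0.15, 0.20]
aggregate: centroid
models: [gblup, ssgblup, wgblup]
varcomp: "true"
replicates: 5
master_seed: 1
baseline: true
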