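# Worked-example pipeline config. Paths are relative to this file.
cells: example_cells.tsv
clinical: example_clinical.csv
rules: example_rules.yaml
pairs: example_pairs.tsv
outputDir: spatialTME-results
window: convex_hull
edgeCorrection: border
rMax: 200
densityThreshold: 2
minRef: 5
minTarget: 5
anchor: "CD3+"
clinicalTerms: [smoker, tumor_size_cm]
timeCol: os_months
eventCol: os_event
seed: 1
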