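# Bundled fixtures

Plain-text transcriptions of published summary tables from a Parkinson's
disease QQPPI network study, shipped as inputs for tests and for
`scripts/acceptance.R`:

- `pd_significant_nodes.tsv` — hub and bottleneck gene lists of the two
  QQPPI networks (t-test-derived and SAM-derived branches).
- `pd_reported_markers.tsv` — the subset of those nodes previously
  reported as disease-associated (literature-curated input).
- `pd_degree_moments.tsv` — mean and SD of the degree distributions.
- `pd_network_global.tsv` — printed node and edge counts.
- `pd_complex_coexpression.tsv` — printed group-wise Pearson r values
  for interacting complex-member pairs.
- `pd_complexes_ttest.tsv`, `pd_complexes_sam.tsv` — complex catalogs
  restricted to the published query (clique-forming) proteins, one
  entry per catalog id.
- `pd_neurotransmitters.tsv` — curated marker-neurotransmitter
  association table.
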