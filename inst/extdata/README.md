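# extdata

Drop a ChEMBL v25 activity export for target CHEMBL240 (hERG) here as
`chembl240_v25_activities.tsv` (tab- or comma-separated; ChEMBL web-export
or snake_case column names both work) to enable the curation-funnel and
representative-compound acceptance tests. The file is not bundled: it is a
~18k-row download from ChEMBL and the package runs fully offline without
it.
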