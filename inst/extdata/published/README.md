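# Drop-in location for published reference artifacts

The test suite includes two audits that run against externally published
reference files, which are not distributed with the package. To enable
them, place here:

* `ighv_reference.fasta` — the archived full-length functional human
  IGHV germline reference set (IMGT-gapped or plain FASTA, IUIS-style
  allele names in the headers).
* `asc_thresholds.tsv` — the published allele-specific threshold table,
  tab-separated with columns `allele` and `threshold`.

When these files are absent the corresponding tests report the missing
artifact and fail; all other tests are self-contained.
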