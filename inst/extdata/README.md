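# Optional real-data inputs

Two acceptance checks compare the pipeline against real data and look for
local files in this directory (they fail with a message when the files are
absent; nothing is downloaded):

- `2f8x.pdb` — the DNA-bound Notch transcription complex (PDB entry 2F8X),
  used by the interface hydrogen-bond inventory check (expected chain
  roles: ankyrin domain, RBPJ, MAML-1; adjust the group mapping in the
  test if your copy differs).
- `notch_ank_orthologues.fasta` — two records: the human NOTCH1 ankyrin
  domain followed by the Drosophila Notch ankyrin domain, used by the
  cross-species similarity check.

All other fixtures are generated in code by the package's synthetic-data
module.
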