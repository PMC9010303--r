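# Template chain-role map for a deposited bridged dinucleosome model
# (e.g. a CENP-A nucleosome stack bound by CENP-N). Deposited mmCIF files
# do not carry role annotation, and chain naming varies between entries:
# open the model, check which chains hold the DNA strands, histones and
# factor copies, and edit the ids below before use. The layout shown is
# the common two-nucleosome convention (histones A-H / a-h, DNA I,J / i,j,
# factors K,L); it is a template authored for illustration, not a record
# of any specific PDB entry.
nucleosomes:
  nuc1:
    dna: [I, J]
    histones: {A: CENP-A, B: H4, C: H2A, D: H2B, E: CENP-A, F: H4, G: H2A, H: H2B}
    flexible: false
    flexible_bp_per_end: 0
  nuc2:
    dna: [i, j]
    histones: {a: CENP-A, b: H4, c: H2A, d: H2B, e: CENP-A, f: H4, g: H2A, h: H2B}
    flexible: false
    flexible_bp_per_end: 0
factors:
  f1: {chain: K, label: CENP-N}
  f2: {chain: L, label: CENP-N}
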