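# MD-directed dual-receptor coagonist design: GLP-1R-oriented mutation set
# (including R17Q) on the 29-residue glucagon template, positions 3 and 15
# set back to Glu to match GLP-1, then the C-terminal graft of GLP-1(7-37)
# positions 30-31 (Arg, Gly) -> 31-residue coagonist. The position-16
# substitution is a parameter (S16W from the GLP-1R-oriented base; edit to
# S16M for the GCGR-oriented variant).
name: MDD_GR
template: glucagon
mutations: [S16W, Q24D, N28D, R17Q]
back_mutations: [Q3E, D15E]
graft:
  donor: glp1_7_37
  from: 30
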