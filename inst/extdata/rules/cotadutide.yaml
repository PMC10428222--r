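# Clinical-stage dual-agonist reference: glucagon template with
# substitutions at positions 10, 12, 17, 20, 24, 27, 28 and an appended
# C-terminal Gly30 (fatty-acid modification not modelled). 30 residues.
name: Cotadutide
template: glucagon
mutations: [Y10K, K12E, R17E, Q20K, Q24E, M27E, N28S]
back_mutations: []
graft:
  donor: G
  from: 1
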