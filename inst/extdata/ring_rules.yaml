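# RING domain detection/classification rules.
#
# Each subtype lists the residues accepted at the eight zinc-coordinating
# metal-ligand positions (ML1..ML8) and the inclusive range of residues
# allowed between consecutive ligands (7 inter-ligand gaps). Subtypes are
# matched in the order given. A residue entry may contain several letters
# (any of them is accepted at that position).
#
# RING-v and RING-G are editable placeholder rules: verify them against the
# subtype classification scheme you adopt before using them on real data.
max_domain_span: 102
incomplete_policy: flag      # flag: emit INCOMPLETE candidates; drop: discard them
min_ligand_matches: 6        # candidate chains matching >= this many ligands are kept
subtypes:
  - name: RING-H2
    residues: [C, C, C, H, H, C, C, C]
    gaps: [[2, 2], [9, 39], [1, 3], [2, 3], [2, 2], [4, 48], [2, 2]]
    rbx_substitution: {position: 8, residue: D}
  - name: RING-HC
    residues: [C, C, C, H, C, C, C, C]
    gaps: [[2, 2], [9, 39], [1, 3], [2, 3], [2, 2], [4, 48], [2, 2]]
  - name: RING-v
    residues: [C, C, C, C, H, C, C, C]
    gaps: [[2, 2], [9, 39], [1, 3], [1, 4], [2, 2], [2, 48], [2, 2]]
  - name: RING-G
    residues: [C, C, C, H, G, C, C, C]
    gaps: [[2, 2], [9, 39], [1, 3], [2, 3], [2, 2], [4, 48], [2, 2]]
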