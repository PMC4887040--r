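# Flexible catalytic-triad model for the hydrolysis of cephalexin: one
# backbone oxyanion donor is replaced by a tyrosine hydroxyl, a serine
# hydroxyl stabilizes the triad aspartate, and a glutamate (instead of an
# aspartate) stabilizes the substrate's alpha-amino group.  The added side
# chains carry torsional freedom, so larger substrates can be accommodated.
name: cephalexin_flexible
ts: cephalexin_ts.yaml
residues:
- {role: SER1, aa: SER, class: catalytic, via: side_chain}
- {role: HIS2, aa: HIS, class: catalytic, via: side_chain}
- {role: ASP3, aa: ASP, class: catalytic, via: side_chain}
- {role: ALA4, aa: ANY, class: stabilizes_TS, via: backbone}
- {role: TYR5, aa: TYR, class: stabilizes_TS, via: side_chain}
- {role: SER6, aa: SER, class: stabilizes_catalytic, via: side_chain}
- {role: GLU7, aa: GLU, class: stabilizes_TS, via: side_chain}
constraints:
- {kind: distance, atoms: ["SER1:OG", "TS:C1"], optimal: 2.6, tolerance: 0.3}
- {kind: angle, atoms: ["SER1:CB", "SER1:OG", "TS:C1"], optimal: 109.5, tolerance: 15.0}
- {kind: angle, atoms: ["SER1:OG", "TS:C1", "TS:O1"], optimal: 100.0, tolerance: 15.0}
- {kind: distance, atoms: ["HIS2:NE2", "SER1:OG"], optimal: 3.0, tolerance: 0.3}
- {kind: angle, atoms: ["SER1:CB", "SER1:OG", "HIS2:NE2"], optimal: 109.5, tolerance: 15.0}
- {kind: angle, atoms: ["SER1:OG", "HIS2:NE2", "HIS2:CD2"], optimal: 127.0, tolerance: 20.0}
- {kind: distance, atoms: ["ASP3:OD2", "HIS2:ND1"], optimal: 2.8, tolerance: 0.3}
- {kind: angle, atoms: ["ASP3:CG", "ASP3:OD2", "HIS2:ND1"], optimal: 120.0, tolerance: 15.0}
- {kind: distance, atoms: ["ALA4:N", "TS:O1"], optimal: 2.9, tolerance: 0.3}
- {kind: angle, atoms: ["ALA4:N", "ALA4:HN", "TS:O1"], optimal: 180.0, tolerance: 40.0}
- {kind: distance, atoms: ["TYR5:OH", "TS:O1"], optimal: 2.7, tolerance: 0.3}
- {kind: angle, atoms: ["TYR5:CZ", "TYR5:OH", "TS:O1"], optimal: 115.0, tolerance: 20.0}
- {kind: distance, atoms: ["SER6:OG", "ASP3:OD1"], optimal: 2.7, tolerance: 0.3}
- {kind: angle, atoms: ["SER6:CB", "SER6:OG", "ASP3:OD1"], optimal: 110.0, tolerance: 20.0}
- {kind: distance, atoms: ["GLU7:OE1", "TS:NA1"], optimal: 2.8, tolerance: 0.3}
- {kind: angle, atoms: ["GLU7:CD", "GLU7:OE1", "TS:NA1"], optimal: 120.0, tolerance: 15.0}
- {kind: improper_dihedral, atoms: ["SER1:OG", "TS:O1", "TS:C1", "TS:NL"], optimal: 120.0, tolerance: 15.0}
- {kind: angle, atoms: ["ALA4:N", "TS:O1", "TS:C1"], optimal: 120.0, tolerance: 20.0}
- {kind: improper_dihedral, atoms: ["SER1:CB", "SER1:OG", "HIS2:NE2", "HIS2:CD2"], optimal: 120.0, tolerance: 20.0}
- {kind: improper_dihedral, atoms: ["SER1:OG", "HIS2:NE2", "HIS2:CD2", "HIS2:CG"], optimal: 180.0, tolerance: 20.0}
- {kind: improper_dihedral, atoms: ["HIS2:CE1", "HIS2:CG", "HIS2:ND1", "ASP3:OD2"], optimal: 180.0, tolerance: 20.0}
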