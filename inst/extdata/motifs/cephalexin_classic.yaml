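# Classic catalytic-triad model for the hydrolysis of cephalexin: the PNPA
# motif plus an extra aspartate stabilizing the positively charged
# alpha-amino group of the substrate.
name: cephalexin_classic
ts: cephalexin_ts.yaml
residues:
- {role: SER1, aa: SER, class: catalytic, via: side_chain}
- {role: HIS2, aa: HIS, class: catalytic, via: side_chain}
- {role: ASP3, aa: ASP, class: catalytic, via: side_chain}
- {role: ALA4, aa: ANY, class: stabilizes_TS, via: backbone}
- {role: ALA5, aa: ANY, class: stabilizes_TS, via: backbone}
- {role: ALA6, aa: ANY, class: stabilizes_catalytic, via: backbone}
- {role: ASP7, aa: ASP, class: stabilizes_TS, via: side_chain}
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
- {kind: distance, atoms: ["ALA5:N", "TS:O1"], optimal: 2.9, tolerance: 0.3}
- {kind: angle, atoms: ["ALA5:N", "ALA5:HN", "TS:O1"], optimal: 180.0, tolerance: 40.0}
- {kind: distance, atoms: ["ALA6:N", "ASP3:OD1"], optimal: 2.9, tolerance: 0.3}
- {kind: angle, atoms: ["ALA6:N", "ALA6:HN", "ASP3:OD1"], optimal: 180.0, tolerance: 40.0}
- {kind: distance, atoms: ["ASP7:OD1", "TS:NA1"], optimal: 2.8, tolerance: 0.3}
- {kind: angle, atoms: ["ASP7:CG", "ASP7:OD1", "TS:NA1"], optimal: 120.0, tolerance: 15.0}
- {kind: improper_dihedral, atoms: ["SER1:OG", "TS:O1", "TS:C1", "TS:NL"], optimal: 120.0, tolerance: 15.0}
- {kind: angle, atoms: ["ALA4:N", "TS:O1", "TS:C1"], optimal: 120.0, tolerance: 20.0}
- {kind: angle, atoms: ["ALA6:N", "ASP3:OD1", "ASP3:CG"], optimal: 120.0, tolerance: 20.0}
- {kind: angle, atoms: ["ALA5:N", "TS:O1", "TS:C1"], optimal: 120.0, tolerance: 20.0}
- {kind: improper_dihedral, atoms: ["SER1:CB", "SER1:OG", "HIS2:NE2", "HIS2:CD2"], optimal: 120.0, tolerance: 20.0}
- {kind: improper_dihedral, atoms: ["SER1:OG", "HIS2:NE2", "HIS2:CD2", "HIS2:CG"], optimal: 180.0, tolerance: 20.0}
- {kind: improper_dihedral, atoms: ["HIS2:CE1", "HIS2:CG", "HIS2:ND1", "ASP3:OD2"], optimal: 180.0, tolerance: 20.0}
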