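# Tetrahedral-intermediate model for the hydrolysis of p-nitrophenyl
# acetate (PNPA): tetrahedral carbon C1 with oxyanion O1, aryl ester oxygen
# O2 leading to the p-nitrophenyl ring, and the acetyl methyl CM.
# Geometry idealized; charges are surrogate CHARMM-style/PARSE-style values.
name: pnpa_ts
charge_set: charmm
atoms:
- {name: C1, element: C, charge: 0.60, charge_parse: 0.55}
- {name: O1, element: O, charge: -0.90, charge_parse: -0.95}
- {name: O2, element: O, charge: -0.40, charge_parse: -0.45}
- {name: CM, element: C, charge: -0.25, charge_parse: -0.20}
- {name: CA1, element: C, charge: 0.10, charge_parse: 0.10}
- {name: CB1, element: C, charge: -0.115, charge_parse: -0.10}
- {name: CB2, element: C, charge: -0.115, charge_parse: -0.10}
- {name: CC1, element: C, charge: -0.115, charge_parse: -0.10}
- {name: CC2, element: C, charge: -0.115, charge_parse: -0.10}
- {name: CD1, element: C, charge: 0.05, charge_parse: 0.05}
- {name: NN, element: N, charge: 0.50, charge_parse: 0.55}
- {name: ON1, element: O, charge: -0.40, charge_parse: -0.45}
- {name: ON2, element: O, charge: -0.40, charge_parse: -0.45}
zmatrix:
- {atom: C1}
- {atom: O1, ref: [C1], length: 1.30}
- {atom: O2, ref: [O1, C1], length: 1.42, angle: 109.5}
- {atom: CM, ref: [O2, O1, C1], length: 1.52, angle: 109.5, torsion: 120.0}
- {atom: CA1, ref: [O1, C1, O2], length: 1.41, angle: 118.0, torsion: 180.0}
- {atom: CB1, ref: [C1, O2, CA1], length: 1.39, angle: 120.0, torsion: 90.0}
- {atom: CB2, ref: [CB1, O2, CA1], length: 1.39, angle: 120.0, torsion: 180.0}
- {atom: CC1, ref: [O2, CA1, CB1], length: 1.39, angle: 120.0, torsion: 180.0}
- {atom: CC2, ref: [O2, CA1, CB2], length: 1.39, angle: 120.0, torsion: 180.0}
- {atom: CD1, ref: [CA1, CB1, CC1], length: 1.39, angle: 120.0, torsion: 0.0}
- {atom: NN, ref: [CB1, CC1, CD1], length: 1.46, angle: 120.0, torsion: 180.0}
- {atom: ON1, ref: [CC1, CD1, NN], length: 1.23, angle: 118.0, torsion: 0.0}
- {atom: ON2, ref: [ON1, CD1, NN], length: 1.23, angle: 118.0, torsion: 180.0}
rotatable: [CB1]
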