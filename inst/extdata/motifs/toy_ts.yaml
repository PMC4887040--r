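# Toy transition-state model: a rigid 6-atom tetrahedral-intermediate
# fragment with an oxyanion-like acceptor (O1), an ester-type oxygen (O2)
# and two carbon substituents.  Synthetic test ligand, not derived from any
# crystal structure.
name: toy_ts
charge_set: charmm
atoms:
- {name: C1, element: C, charge: 0.60, charge_parse: 0.55}
- {name: O1, element: O, charge: -0.90, charge_parse: -0.95}
- {name: O2, element: O, charge: -0.40, charge_parse: -0.45}
- {name: C2, element: C, charge: -0.20, charge_parse: -0.15}
- {name: C3, element: C, charge: 0.10, charge_parse: 0.15}
- {name: C4, element: C, charge: -0.20, charge_parse: -0.15}
zmatrix:
- {atom: C1}
- {atom: O1, ref: [C1], length: 1.30}
- {atom: O2, ref: [O1, C1], length: 1.42, angle: 109.5}
- {atom: C2, ref: [O2, O1, C1], length: 1.52, angle: 109.5, torsion: 120.0}
- {atom: C3, ref: [O1, C1, O2], length: 1.44, angle: 117.0, torsion: 180.0}
- {atom: C4, ref: [C1, O2, C3], length: 1.50, angle: 111.0, torsion: 180.0}
rotatable: []
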