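# Reduced tetrahedral-intermediate model for the hydrolysis of cephalexin:
# tetrahedral carbon C1 with oxyanion O1, the scissile amide nitrogen NL
# (leading to the dihydrothiazine-ring stub), and the phenylglycyl side with
# its positively charged alpha-amino group NA1.  Heavy-atom fragment;
# ring systems are represented by stubs.
name: cephalexin_ts
charge_set: charmm
atoms:
- {name: C1, element: C, charge: 0.60, charge_parse: 0.55}
- {name: O1, element: O, charge: -0.90, charge_parse: -0.95}
- {name: NL, element: N, charge: -0.45, charge_parse: -0.50}
- {name: CA2, element: C, charge: 0.05, charge_parse: 0.05}
- {name: CS1, element: C, charge: -0.10, charge_parse: -0.10}
- {name: SG1, element: S, charge: -0.15, charge_parse: -0.15}
- {name: CAL, element: C, charge: 0.10, charge_parse: 0.10}
- {name: NA1, element: N, charge: -0.30, charge_parse: -0.30}
- {name: CP1, element: C, charge: 0.00, charge_parse: 0.00}
- {name: CP2, element: C, charge: -0.115, charge_parse: -0.10}
- {name: CP3, element: C, charge: -0.115, charge_parse: -0.10}
- {name: CP4, element: C, charge: -0.115, charge_parse: -0.10}
zmatrix:
- {atom: C1}
- {atom: O1, ref: [C1], length: 1.30}
- {atom: NL, ref: [O1, C1], length: 1.48, angle: 108.0}
- {atom: CAL, ref: [NL, O1, C1], length: 1.53, angle: 110.0, torsion: 118.0}
- {atom: CA2, ref: [O1, C1, NL], length: 1.46, angle: 115.0, torsion: 150.0}
- {atom: CS1, ref: [C1, NL, CA2], length: 1.52, angle: 112.0, torsion: -90.0}
- {atom: SG1, ref: [NL, CA2, CS1], length: 1.81, angle: 113.0, torsion: 180.0}
- {atom: NA1, ref: [NL, C1, CAL], length: 1.49, angle: 110.0, torsion: 60.0}
- {atom: CP1, ref: [NA1, C1, CAL], length: 1.52, angle: 111.0, torsion: -120.0}
- {atom: CP2, ref: [C1, CAL, CP1], length: 1.39, angle: 120.0, torsion: 90.0}
- {atom: CP3, ref: [CP2, CAL, CP1], length: 1.39, angle: 120.0, torsion: 180.0}
- {atom: CP4, ref: [CAL, CP1, CP2], length: 1.39, angle: 120.0, torsion: 180.0}
rotatable: [CP2]
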