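# Species/role map for CHARMM36-style residue and atom names.
# Only atoms carrying an analysis role need to be listed; any other atom
# of a mapped residue is kept without a role.
residues:
  POPC: POPC
  POPE: POPE
  POPS: POPS
  SAPI24: PIP2
  PIP2: PIP2
  TIP3: WATER
  SOD: "NA"
  CLA: CL
atoms:
  POPC:
    P: P
    O13: OP1
    O14: OP2
    O11: OP3
    O22: OC1
    O32: OC2
    "N": "N"
    C13: ME1
    C14: ME2
    C15: ME3
    C32: C2
    C33: C3
    C34: C4
    C35: C5
    C36: C6
    C37: C7
    C38: C8
    C39: C9
    C310: C10
    C311: C11
    C312: C12
    C313: C13
    C314: C14
    C315: C15
    C316: C16
    H2X: H2A
    H2Y: H2B
    H3X: H3A
    H3Y: H3B
    H4X: H4A
    H4Y: H4B
    H5X: H5A
    H5Y: H5B
    H6X: H6A
    H6Y: H6B
    H7X: H7A
    H7Y: H7B
    H8X: H8A
    H8Y: H8B
    H9X: H9A
    H9Y: H9B
    H10X: H10A
    H10Y: H10B
    H11X: H11A
    H11Y: H11B
    H12X: H12A
    H12Y: H12B
    H13X: H13A
    H13Y: H13B
    H14X: H14A
    H14Y: H14B
    H15X: H15A
    H15Y: H15B
    H16X: H16A
    H16Y: H16B
  POPE:
    P: P
    O13: OP1
    O14: OP2
    O11: OP3
    O22: OC1
    O32: OC2
    "N": "N"
    HN1: HN1
    HN2: HN2
    HN3: HN3
    C32: C2
    C33: C3
    C34: C4
    C35: C5
    C36: C6
    C37: C7
    C38: C8
    C39: C9
    C310: C10
    C311: C11
    C312: C12
    C313: C13
    C314: C14
    C315: C15
    C316: C16
    H2X: H2A
    H2Y: H2B
    H3X: H3A
    H3Y: H3B
    H4X: H4A
    H4Y: H4B
    H5X: H5A
    H5Y: H5B
    H6X: H6A
    H6Y: H6B
    H7X: H7A
    H7Y: H7B
    H8X: H8A
    H8Y: H8B
    H9X: H9A
    H9Y: H9B
    H10X: H10A
    H10Y: H10B
    H11X: H11A
    H11Y: H11B
    H12X: H12A
    H12Y: H12B
    H13X: H13A
    H13Y: H13B
    H14X: H14A
    H14Y: H14B
    H15X: H15A
    H15Y: H15B
    H16X: H16A
    H16Y: H16B
  POPS:
    P: P
    O13: OP1
    O14: OP2
    O11: OP3
    O22: OC1
    O32: OC2
    "N": "N"
    HN1: HN1
    HN2: HN2
    HN3: HN3
    O13A: OCA
    O13B: OCB
    C32: C2
    C33: C3
    C34: C4
    C35: C5
    C36: C6
    C37: C7
    C38: C8
    C39: C9
    C310: C10
    C311: C11
    C312: C12
    C313: C13
    C314: C14
    C315: C15
    C316: C16
    H2X: H2A
    H2Y: H2B
    H3X: H3A
    H3Y: H3B
    H4X: H4A
    H4Y: H4B
    H5X: H5A
    H5Y: H5B
    H6X: H6A
    H6Y: H6B
    H7X: H7A
    H7Y: H7B
    H8X: H8A
    H8Y: H8B
    H9X: H9A
    H9Y: H9B
    H10X: H10A
    H10Y: H10B
    H11X: H11A
    H11Y: H11B
    H12X: H12A
    H12Y: H12B
    H13X: H13A
    H13Y: H13B
    H14X: H14A
    H14Y: H14B
    H15X: H15A
    H15Y: H15B
    H16X: H16A
    H16Y: H16B
  PIP2:
    P: P
    O13: OP1
    O14: OP2
    O11: OP3
    O22: OC1
    O32: OC2
    C2: C2I
    C5: C5I
    OP33: O3A
    OP34: O3B
    OP43: O4A
    O6: O6I
    HO6: HO6
    C32: C2
    C33: C3
    C34: C4
    C35: C5
    C36: C6
    C37: C7
    C38: C8
    C39: C9
    C310: C10
    C311: C11
    C312: C12
    C313: C13
    C314: C14
    C315: C15
    C316: C16
    H2X: H2A
    H2Y: H2B
    H3X: H3A
    H3Y: H3B
    H4X: H4A
    H4Y: H4B
    H5X: H5A
    H5Y: H5B
    H6X: H6A
    H6Y: H6B
    H7X: H7A
    H7Y: H7B
    H8X: H8A
    H8Y: H8B
    H9X: H9A
    H9Y: H9B
    H10X: H10A
    H10Y: H10B
    H11X: H11A
    H11Y: H11B
    H12X: H12A
    H12Y: H12B
    H13X: H13A
    H13Y: H13B
    H14X: H14A
    H14Y: H14B
    H15X: H15A
    H15Y: H15B
    H16X: H16A
    H16Y: H16B
  WATER:
    OH2: OW
    H1: HW1
    H2: HW2
  "NA":
    SOD: "NA"
  CL:
    CLA: CL
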