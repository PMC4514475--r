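# Hydrogen-bond donor/acceptor templates by residue name.
# donors: heavy atom plus the hydrogens bonded to it (hydrogen names as
# they appear in the coordinates, if present); acceptors: heavy atoms.
# BACKBONE entries are merged into every protein residue.
BACKBONE:
  donors:
    - atom: "N"
      hydrogens: ["H", HN]
  acceptors: [O, OXT]
HOH:
  donors:
    - atom: O
      hydrogens: [H1, H2]
    - atom: OH2
      hydrogens: [H1, H2]
    - atom: OW
      hydrogens: [HW1, HW2]
  acceptors: [O, OH2, OW]
SER:
  donors:
    - atom: OG
      hydrogens: [HG1, HG]
  acceptors: [OG]
THR:
  donors:
    - atom: OG1
      hydrogens: [HG1]
  acceptors: [OG1]
TYR:
  donors:
    - atom: OH
      hydrogens: [HH]
  acceptors: [OH]
LYS:
  donors:
    - atom: NZ
      hydrogens: [HZ1, HZ2, HZ3]
  acceptors: []
ARG:
  donors:
    - atom: NE
      hydrogens: [HE]
    - atom: NH1
      hydrogens: [HH11, HH12]
    - atom: NH2
      hydrogens: [HH21, HH22]
  acceptors: []
TRP:
  donors:
    - atom: NE1
      hydrogens: [HE1]
  acceptors: []
HIS:
  donors:
    - atom: ND1
      hydrogens: [HD1]
    - atom: NE2
      hydrogens: [HE2]
  acceptors: [ND1, NE2]
ASN:
  donors:
    - atom: ND2
      hydrogens: [HD21, HD22]
  acceptors: [OD1]
GLN:
  donors:
    - atom: NE2
      hydrogens: [HE21, HE22]
  acceptors: [OE1]
ASP:
  donors: []
  acceptors: [OD1, OD2]
GLU:
  donors: []
  acceptors: [OE1, OE2]
CYS:
  donors:
    - atom: SG
      hydrogens: [HG1, HG]
  acceptors: [SG]
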