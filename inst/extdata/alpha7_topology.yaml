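chain_ids:
- A
- B
- C
- D
- E
prime_map:
  '-2': 231
  '-1': 232
  '0': 233
  '1': 234
  '2': 235
  '3': 236
  '4': 237
  '5': 238
  '6': 239
  '7': 240
  '8': 241
  '9': 242
  '10': 243
  '11': 244
  '12': 245
  '13': 246
  '14': 247
  '15': 248
  '16': 249
  '17': 250
  '18': 251
  '19': 252
  '20': 253
m2_range:
- 231
- 253
loops:
  C_loop:
  - 179
  - 188
  Cys_loop:
  - 122
  - 136
  beta1_beta2:
  - 38
  - 44
  M2_M3:
  - 254
  - 258
  backwall:
  - 139
  - 140
ligand_resname: EPI
key_residues:
  Pro256: 256
  Lys40: 40
  Tyr87: 87
  Leu103: 103
  Leu113: 113
  Trp143: 143
  Tyr182: 182
  Tyr189: 189
  Val13p: 246
  Leu16p: 249
  Leu9p: 242
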