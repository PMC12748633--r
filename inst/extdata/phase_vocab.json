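{
 "provenance": "Single-phase labels, descriptions and literature aliases transcribed from the published PhDat label table; lamellar aliases D and G added from the accompanying text. The canonical state list was recovered from the published run-together state table by longest-match tokenization over the label set; five trailing cells are exact duplicates of earlier cells and were dropped, and one ambiguous run-together cell ('V2iV2p+X1') is retained as printed with its first token flagged as a provisional label, reconciling the list to the published count of 118 distinct states (excluding the reserved unknown label U).",
 "labels": [
  {
   "code": "E",
   "description": "Ice",
   "aliases": [
    "Ice"
   ]
  },
  {
   "code": "H1",
   "description": "Hexagonal phase",
   "aliases": [
    "H_1"
   ]
  },
  {
   "code": "H2",
   "description": "Inverse hexagonal phase",
   "aliases": [
    "H_2"
   ]
  },
  {
   "code": "I1",
   "description": "Cubic micellar phase",
   "aliases": [
    "I_1"
   ]
  },
  {
   "code": "I2",
   "description": "Inverse cubic micellar phase",
   "aliases": [
    "I_2"
   ]
  },
  {
   "code": "L1",
   "description": "Isotropic micellar solution",
   "aliases": [
    "L_1"
   ]
  },
  {
   "code": "L2",
   "description": "Isotropic reverse micellar solution",
   "aliases": [
    "L_2"
   ]
  },
  {
   "code": "L3",
   "description": "Sponge phase",
   "aliases": [
    "L_3"
   ]
  },
  {
   "code": "La",
   "description": "Lamellar phase",
   "aliases": [
    "L_α",
    "D",
    "G"
   ]
  },
  {
   "code": "La1",
   "description": "Lamellar phase",
   "aliases": [
    "Soap Boilers Neat Soap"
   ]
  },
  {
   "code": "La2",
   "description": "Lamellar phase",
   "aliases": [
    "Superneat Soap"
   ]
  },
  {
   "code": "Lb",
   "description": "Gel phase",
   "aliases": [
    "L_β"
   ]
  },
  {
   "code": "M1",
   "description": "2D monoclinic phase",
   "aliases": [
    "M_α"
   ]
  },
  {
   "code": "N1",
   "description": "Nematic liquid of rod- or worm-like micelles",
   "aliases": [
    "N_1"
   ]
  },
  {
   "code": "Pb",
   "description": "Hydrated bilayer-based rippled phase",
   "aliases": [
    "P_β’"
   ]
  },
  {
   "code": "R1",
   "description": "Rhombohedral phase",
   "aliases": [
    "R_α"
   ]
  },
  {
   "code": "S",
   "description": "Non-crystalline solid",
   "aliases": [
    "Neat Soap"
   ]
  },
  {
   "code": "Sa",
   "description": "Non-crystalline solid",
   "aliases": [
    "S_α"
   ]
  },
  {
   "code": "Sb",
   "description": "Non-crystalline solid",
   "aliases": [
    "S_β"
   ]
  },
  {
   "code": "T1",
   "description": "Tetragonal phase",
   "aliases": [
    "T_α"
   ]
  },
  {
   "code": "V1",
   "description": "Bicontinuous cubic phase",
   "aliases": [
    "V_1"
   ]
  },
  {
   "code": "V2",
   "description": "Inverse bicontinuous phase",
   "aliases": [
    "V_2"
   ]
  },
  {
   "code": "V2i",
   "description": "Inverse bicontinuous phase with space group Pn3m",
   "aliases": [
    "V2_i"
   ]
  },
  {
   "code": "V2m",
   "description": "Inverse bicontinuous phase with space group Ia3d",
   "aliases": [
    "V2_m"
   ]
  },
  {
   "code": "V2p",
   "description": "Inverse bicontinuous phase with space group Im3m",
   "aliases": [
    "V2_p"
   ]
  },
  {
   "code": "W",
   "description": "Water phase or sub-micellar solution",
   "aliases": [
    "Water"
   ]
  },
  {
   "code": "X",
   "description": "Generic crystalline (solid) surfactant phase",
   "aliases": []
  },
  {
   "code": "X1",
   "description": "Solid surfactant phase (hydration state 1)",
   "aliases": [
    "X_1"
   ]
  },
  {
   "code": "X2",
   "description": "Solid surfactant phase (hydration state 2)",
   "aliases": [
    "X_2"
   ]
  },
  {
   "code": "X3",
   "description": "Solid surfactant phase (hydration state 3)",
   "aliases": [
    "X_3"
   ]
  },
  {
   "code": "X4",
   "description": "Solid surfactant phase (hydration state 4)",
   "aliases": [
    "X_4"
   ]
  },
  {
   "code": "X5",
   "description": "Solid surfactant phase (hydration state 5)",
   "aliases": [
    "X_5"
   ]
  },
  {
   "code": "X6",
   "description": "Solid surfactant phase (hydration state 6)",
   "aliases": [
    "X_6"
   ]
  },
  {
   "code": "Xa",
   "description": "Solid surfactant phase (variant a)",
   "aliases": [
    "X_a"
   ]
  },
  {
   "code": "Xb",
   "description": "Solid surfactant phase (variant b)",
   "aliases": [
    "X_b"
   ]
  },
  {
   "code": "U",
   "description": "Unmeasured / unknown / unclear region or phase state",
   "aliases": [
    "Unknown"
   ]
  },
  {
   "code": "V2iV2p",
   "description": "Composite cell retained as printed from the published state table; probable typesetting artifact involving the V2i and V2p labels. Flagged provisional; kept so the canonical state list reconciles to its published count.",
   "aliases": [],
   "provisional": true
  }
 ],
 "states": [
  "E+H1",
  "E+I1",
  "E+L1",
  "E+L2",
  "E+La",
  "E+V1",
  "E+X",
  "E+X1",
  "E+X2",
  "E+X3",
  "H1",
  "H1+V2",
  "H1+L1",
  "H1+La",
  "H1+La1",
  "H1+R1",
  "H1+V1",
  "H1+X2",
  "H1+X1",
  "H1+I1",
  "H1+X4",
  "H2",
  "H2+L1",
  "H2+X1",
  "H2+W",
  "H2+V2p",
  "I1",
  "I1+X1",
  "I1+X4",
  "I1+X5",
  "I1+T1",
  "I1+La",
  "I2",
  "L1",
  "L1+L3",
  "L1+La",
  "L1+La1",
  "L1+Lb",
  "L1+V1",
  "L1+W",
  "L1+X",
  "L1+X1",
  "L1+X2",
  "L1+X3",
  "L1+X4",
  "L1+X6",
  "L1+Sa",
  "L2",
  "L2+La",
  "L2+Lb",
  "L2+W",
  "L2+X1",
  "L2+Xa",
  "L2+V2i",
  "L3",
  "L3+La",
  "L3+W",
  "L3+X1",
  "La",
  "La1",
  "La2",
  "La1+La2",
  "La+S",
  "La+Sa",
  "La+Sb",
  "La+T1",
  "La+V2i",
  "La+V2p",
  "La+W",
  "La+X",
  "La+Xb",
  "La+X1",
  "La+X2",
  "La+X3",
  "La+X4",
  "Lb",
  "Lb+Pb",
  "Lb+W",
  "N1",
  "M1",
  "M1+X1",
  "Pb",
  "Pb+W",
  "R1",
  "R1+X1",
  "S",
  "Sa",
  "Sb",
  "Sa+Sb",
  "S+X1",
  "T1",
  "T1+X1",
  "V1",
  "V1+X1",
  "V2",
  "V2iV2p",
  "V2i+V2p",
  "V2+W",
  "V2p+W",
  "V2+X1",
  "V2i+X1",
  "V2p+X1",
  "V2iV2p+X1",
  "V2p",
  "W+X1",
  "W+X2",
  "X",
  "X1",
  "X1+X2",
  "X2",
  "X2+X3",
  "X3",
  "X3+X4",
  "X4",
  "X5",
  "X6",
  "Xa",
  "Xb"
 ]
}
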