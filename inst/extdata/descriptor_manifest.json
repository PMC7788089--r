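{
 "engine": "rdkit",
 "engine_version": "2024.09.2",
 "n_descriptors": 123,
 "descriptors": [
  {
   "name": "MolWt",
   "group": "atom-based"
  },
  {
   "name": "HeavyAtomMolWt",
   "group": "atom-based"
  },
  {
   "name": "HeavyAtomCount",
   "group": "atom-based"
  },
  {
   "name": "NumHAtoms",
   "group": "atom-based"
  },
  {
   "name": "NumC",
   "group": "atom-based"
  },
  {
   "name": "NumN",
   "group": "atom-based"
  },
  {
   "name": "NumO",
   "group": "atom-based"
  },
  {
   "name": "NumS",
   "group": "atom-based"
  },
  {
   "name": "NumP",
   "group": "atom-based"
  },
  {
   "name": "NumF",
   "group": "atom-based"
  },
  {
   "name": "NumCl",
   "group": "atom-based"
  },
  {
   "name": "NumBr",
   "group": "atom-based"
  },
  {
   "name": "NumI",
   "group": "atom-based"
  },
  {
   "name": "NumHalogen",
   "group": "atom-based"
  },
  {
   "name": "NumHeteroatoms",
   "group": "atom-based"
  },
  {
   "name": "FractionCSP3",
   "group": "atom-based"
  },
  {
   "name": "NHOHCount",
   "group": "atom-based"
  },
  {
   "name": "NOCount",
   "group": "atom-based"
  },
  {
   "name": "NumRadicalElectrons",
   "group": "atom-based"
  },
  {
   "name": "RingCount",
   "group": "ring-based"
  },
  {
   "name": "NumAromaticRings",
   "group": "ring-based"
  },
  {
   "name": "NumAliphaticRings",
   "group": "ring-based"
  },
  {
   "name": "NumSaturatedRings",
   "group": "ring-based"
  },
  {
   "name": "NumAromaticCarbocycles",
   "group": "ring-based"
  },
  {
   "name": "NumAromaticHeterocycles",
   "group": "ring-based"
  },
  {
   "name": "NumBonds",
   "group": "bond-based"
  },
  {
   "name": "NumSingleBonds",
   "group": "bond-based"
  },
  {
   "name": "NumDoubleBonds",
   "group": "bond-based"
  },
  {
   "name": "NumTripleBonds",
   "group": "bond-based"
  },
  {
   "name": "NumAromaticBonds",
   "group": "bond-based"
  },
  {
   "name": "NumRingBonds",
   "group": "bond-based"
  },
  {
   "name": "NumRotatableBonds",
   "group": "bond-based"
  },
  {
   "name": "NumHDonors",
   "group": "bond-based"
  },
  {
   "name": "NumHAcceptors",
   "group": "bond-based"
  },
  {
   "name": "MolLogP",
   "group": "logp"
  },
  {
   "name": "BalabanJ",
   "group": "topological"
  },
  {
   "name": "BertzCT",
   "group": "topological"
  },
  {
   "name": "Chi0",
   "group": "topological"
  },
  {
   "name": "Chi1",
   "group": "topological"
  },
  {
   "name": "Chi0n",
   "group": "topological"
  },
  {
   "name": "Chi1n",
   "group": "topological"
  },
  {
   "name": "Chi2n",
   "group": "topological"
  },
  {
   "name": "Chi3n",
   "group": "topological"
  },
  {
   "name": "Chi4n",
   "group": "topological"
  },
  {
   "name": "Chi0v",
   "group": "topological"
  },
  {
   "name": "Chi1v",
   "group": "topological"
  },
  {
   "name": "Chi2v",
   "group": "topological"
  },
  {
   "name": "Chi3v",
   "group": "topological"
  },
  {
   "name": "Chi4v",
   "group": "topological"
  },
  {
   "name": "HallKierAlpha",
   "group": "topological"
  },
  {
   "name": "Kappa1",
   "group": "topological"
  },
  {
   "name": "Kappa2",
   "group": "topological"
  },
  {
   "name": "Kappa3",
   "group": "topological"
  },
  {
   "name": "EState_ssBH",
   "group": "e-state"
  },
  {
   "name": "EState_sssB",
   "group": "e-state"
  },
  {
   "name": "EState_ssssB",
   "group": "e-state"
  },
  {
   "name": "EState_sCH3",
   "group": "e-state"
  },
  {
   "name": "EState_dCH2",
   "group": "e-state"
  },
  {
   "name": "EState_ssCH2",
   "group": "e-state"
  },
  {
   "name": "EState_tCH",
   "group": "e-state"
  },
  {
   "name": "EState_dsCH",
   "group": "e-state"
  },
  {
   "name": "EState_aaCH",
   "group": "e-state"
  },
  {
   "name": "EState_sssCH",
   "group": "e-state"
  },
  {
   "name": "EState_ddC",
   "group": "e-state"
  },
  {
   "name": "EState_tsC",
   "group": "e-state"
  },
  {
   "name": "EState_dssC",
   "group": "e-state"
  },
  {
   "name": "EState_aasC",
   "group": "e-state"
  },
  {
   "name": "EState_aaaC",
   "group": "e-state"
  },
  {
   "name": "EState_ssssC",
   "group": "e-state"
  },
  {
   "name": "EState_sNH3",
   "group": "e-state"
  },
  {
   "name": "EState_sNH2",
   "group": "e-state"
  },
  {
   "name": "EState_ssNH2",
   "group": "e-state"
  },
  {
   "name": "EState_dNH",
   "group": "e-state"
  },
  {
   "name": "EState_ssNH",
   "group": "e-state"
  },
  {
   "name": "EState_aaNH",
   "group": "e-state"
  },
  {
   "name": "EState_tN",
   "group": "e-state"
  },
  {
   "name": "EState_sssNH",
   "group": "e-state"
  },
  {
   "name": "EState_dsN",
   "group": "e-state"
  },
  {
   "name": "EState_aaN",
   "group": "e-state"
  },
  {
   "name": "EState_sssN",
   "group": "e-state"
  },
  {
   "name": "EState_ddsN",
   "group": "e-state"
  },
  {
   "name": "EState_aasN",
   "group": "e-state"
  },
  {
   "name": "EState_ssssN",
   "group": "e-state"
  },
  {
   "name": "EState_sOH",
   "group": "e-state"
  },
  {
   "name": "EState_dO",
   "group": "e-state"
  },
  {
   "name": "EState_ssO",
   "group": "e-state"
  },
  {
   "name": "EState_aaO",
   "group": "e-state"
  },
  {
   "name": "EState_sF",
   "group": "e-state"
  },
  {
   "name": "EState_sSiH3",
   "group": "e-state"
  },
  {
   "name": "EState_ssSiH2",
   "group": "e-state"
  },
  {
   "name": "EState_sssSiH",
   "group": "e-state"
  },
  {
   "name": "EState_ssssSi",
   "group": "e-state"
  },
  {
   "name": "EState_sPH2",
   "group": "e-state"
  },
  {
   "name": "EState_ssPH",
   "group": "e-state"
  },
  {
   "name": "EState_sssP",
   "group": "e-state"
  },
  {
   "name": "EState_dsssP",
   "group": "e-state"
  },
  {
   "name": "EState_sssssP",
   "group": "e-state"
  },
  {
   "name": "EState_sSH",
   "group": "e-state"
  },
  {
   "name": "EState_dS",
   "group": "e-state"
  },
  {
   "name": "EState_ssS",
   "group": "e-state"
  },
  {
   "name": "EState_aaS",
   "group": "e-state"
  },
  {
   "name": "EState_dssS",
   "group": "e-state"
  },
  {
   "name": "EState_ddssS",
   "group": "e-state"
  },
  {
   "name": "EState_sCl",
   "group": "e-state"
  },
  {
   "name": "EState_sAsH2",
   "group": "e-state"
  },
  {
   "name": "EState_ssAsH",
   "group": "e-state"
  },
  {
   "name": "EState_sssAs",
   "group": "e-state"
  },
  {
   "name": "EState_sssdAs",
   "group": "e-state"
  },
  {
   "name": "EState_sssssAs",
   "group": "e-state"
  },
  {
   "name": "EState_sSeH",
   "group": "e-state"
  },
  {
   "name": "EState_dSe",
   "group": "e-state"
  },
  {
   "name": "EState_ssSe",
   "group": "e-state"
  },
  {
   "name": "EState_aaSe",
   "group": "e-state"
  },
  {
   "name": "EState_dssSe",
   "group": "e-state"
  },
  {
   "name": "EState_ddssSe",
   "group": "e-state"
  },
  {
   "name": "EState_sBr",
   "group": "e-state"
  },
  {
   "name": "EState_sSnH3",
   "group": "e-state"
  },
  {
   "name": "EState_ssSnH2",
   "group": "e-state"
  },
  {
   "name": "EState_sssSnH",
   "group": "e-state"
  },
  {
   "name": "EState_ssssSn",
   "group": "e-state"
  },
  {
   "name": "EState_sI",
   "group": "e-state"
  },
  {
   "name": "MaxEStateIndex",
   "group": "e-state"
  },
  {
   "name": "MinEStateIndex",
   "group": "e-state"
  }
 ]
}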