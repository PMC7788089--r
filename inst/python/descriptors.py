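"""Compute the 123-descriptor 2D manifest (or InChIKeys) for a SMILES table.

Usage:
    python descriptors.py descriptors IN.csv OUT.csv
    python descriptors.py inchikey    IN.csv OUT.csv
    python descriptors.py manifest    OUT.json

IN.csv must have a header with a `smiles` column. Rows whose SMILES
fail to parse are emitted with an `error` message and empty values;
no row is dropped. Descriptor groups (123 total): atom-based 19,
ring-based 6, bond-based 9, logp 1, topological 18, e-state 70
(68 organic-element atom-type E-state sums + max/min E-state index).
"""
import csv
import json
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Crippen, Descriptors, GraphDescriptors, Lipinski, rdMolDescriptors
from rdkit.Chem.EState import AtomTypes as EStateAtomTypes
from rdkit.Chem.EState import EStateIndices

RDLogger.DisableLog("rdApp.*")

# E-state atom types restricted to organic-chemistry elements: the RDKit
# list minus Li/Be/Ge/Pb types (11 of 79), plus two global extrema -> 70.
_DROP_ESTATE = {
    "sLi", "ssBe", "ssssBe",
    "sGeH3", "ssGeH2", "sssGeH", "ssssGe",
    "sPbH3", "ssPbH2", "sssPbH", "ssssPb",
}


def estate_type_names():
    if EStateAtomTypes.esPatterns is None:
        EStateAtomTypes.BuildPatts()
    return [name for name, _ in EStateAtomTypes.esPatterns if name not in _DROP_ESTATE]


def atom_counts(mol):
    symbols = [a.GetSymbol() for a in mol.GetAtoms()]
    halogens = sum(s in ("F", "Cl", "Br", "I") for s in symbols)
    return {
        "MolWt": Descriptors.MolWt(mol),
        "HeavyAtomMolWt": Descriptors.HeavyAtomMolWt(mol),
        "HeavyAtomCount": mol.GetNumHeavyAtoms(),
        "NumHAtoms": sum(a.GetTotalNumHs() for a in mol.GetAtoms()),
        "NumC": symbols.count("C"),
        "NumN": symbols.count("N"),
        "NumO": symbols.count("O"),
        "NumS": symbols.count("S"),
        "NumP": symbols.count("P"),
        "NumF": symbols.count("F"),
        "NumCl": symbols.count("Cl"),
        "NumBr": symbols.count("Br"),
        "NumI": symbols.count("I"),
        "NumHalogen": halogens,
        "NumHeteroatoms": Lipinski.NumHeteroatoms(mol),
        "FractionCSP3": Lipinski.FractionCSP3(mol),
        "NHOHCount": Lipinski.NHOHCount(mol),
        "NOCount": Lipinski.NOCount(mol),
        "NumRadicalElectrons": Descriptors.NumRadicalElectrons(mol),
    }


def ring_counts(mol):
    return {
        "RingCount": rdMolDescriptors.CalcNumRings(mol),
        "NumAromaticRings": rdMolDescriptors.CalcNumAromaticRings(mol),
        "NumAliphaticRings": rdMolDescriptors.CalcNumAliphaticRings(mol),
        "NumSaturatedRings": rdMolDescriptors.CalcNumSaturatedRings(mol),
        "NumAromaticCarbocycles": rdMolDescriptors.CalcNumAromaticCarbocycles(mol),
        "NumAromaticHeterocycles": rdMolDescriptors.CalcNumAromaticHeterocycles(mol),
    }


def bond_counts(mol):
    bonds = mol.GetBonds()
    by_type = {"SINGLE": 0, "DOUBLE": 0, "TRIPLE": 0, "AROMATIC": 0}
    ring_bonds = 0
    for b in bonds:
        t = str(b.GetBondType())
        if t in by_type:
            by_type[t] += 1
        if b.IsInRing():
            ring_bonds += 1
    return {
        "NumBonds": mol.GetNumBonds(),
        "NumSingleBonds": by_type["SINGLE"],
        "NumDoubleBonds": by_type["DOUBLE"],
        "NumTripleBonds": by_type["TRIPLE"],
        "NumAromaticBonds": by_type["AROMATIC"],
        "NumRingBonds": ring_bonds,
        "NumRotatableBonds": Lipinski.NumRotatableBonds(mol),
        "NumHDonors": Lipinski.NumHDonors(mol),
        "NumHAcceptors": Lipinski.NumHAcceptors(mol),
    }


def topological(mol):
    return {
        "BalabanJ": GraphDescriptors.BalabanJ(mol),
        "BertzCT": GraphDescriptors.BertzCT(mol),
        "Chi0": GraphDescriptors.Chi0(mol),
        "Chi1": GraphDescriptors.Chi1(mol),
        "Chi0n": GraphDescriptors.Chi0n(mol),
        "Chi1n": GraphDescriptors.Chi1n(mol),
        "Chi2n": GraphDescriptors.Chi2n(mol),
        "Chi3n": GraphDescriptors.Chi3n(mol),
        "Chi4n": GraphDescriptors.Chi4n(mol),
        "Chi0v": GraphDescriptors.Chi0v(mol),
        "Chi1v": GraphDescriptors.Chi1v(mol),
        "Chi2v": GraphDescriptors.Chi2v(mol),
        "Chi3v": GraphDescriptors.Chi3v(mol),
        "Chi4v": GraphDescriptors.Chi4v(mol),
        "HallKierAlpha": GraphDescriptors.HallKierAlpha(mol),
        "Kappa1": GraphDescriptors.Kappa1(mol),
        "Kappa2": GraphDescriptors.Kappa2(mol),
        "Kappa3": GraphDescriptors.Kappa3(mol),
    }


def estate(mol):
    names = estate_type_names()
    types = EStateAtomTypes.TypeAtoms(mol)
    indices = EStateIndices(mol)
    sums = dict.fromkeys(("EState_" + n for n in names), 0.0)
    for atom_types, es in zip(types, indices):
        for t in atom_types:
            key = "EState_" + t
            if key in sums:
                sums[key] += float(es)
    n = len(indices)
    sums["MaxEStateIndex"] = float(max(indices)) if n else 0.0
    sums["MinEStateIndex"] = float(min(indices)) if n else 0.0
    return sums


GROUPS = [
    ("atom-based", lambda m: atom_counts(m)),
    ("ring-based", lambda m: ring_counts(m)),
    ("bond-based", lambda m: bond_counts(m)),
    ("logp", lambda m: {"MolLogP": Crippen.MolLogP(m)}),
    ("topological", lambda m: topological(m)),
]


def descriptor_names():
    probe = Chem.MolFromSmiles("CCO")
    names = []
    groups = []
    for gname, fn in GROUPS:
        ks = list(fn(probe).keys())
        names += ks
        groups += [gname] * len(ks)
    es = ["EState_" + n for n in estate_type_names()] + [
        "MaxEStateIndex", "MinEStateIndex"]
    names += es
    groups += ["e-state"] * len(es)
    return names, groups


def compute_row(smiles):
    mol = Chem.MolFromSmiles(smiles) if smiles else None
    if mol is None:
        return None
    vals = {}
    for _, fn in GROUPS:
        vals.update(fn(mol))
    vals.update(estate(mol))
    return vals


def run_descriptors(inp, outp):
    names, _ = descriptor_names()
    with open(inp, newline="") as fi, open(outp, "w", newline="") as fo:
        reader = csv.DictReader(fi)
        writer = csv.writer(fo)
        writer.writerow(["smiles", "error"] + names)
        for row in reader:
            smi = row.get("smiles", "")
            vals = compute_row(smi)
            if vals is None:
                writer.writerow([smi, "unparseable SMILES"] + [""] * len(names))
            else:
                row = [repr(float(vals[n])) if math.isfinite(float(vals[n]))
                       else "" for n in names]
                writer.writerow([smi, ""] + row)


def run_inchikey(inp, outp):
    with open(inp, newline="") as fi, open(outp, "w", newline="") as fo:
        reader = csv.DictReader(fi)
        writer = csv.writer(fo)
        writer.writerow(["smiles", "inchikey", "error"])
        for row in reader:
            smi = row.get("smiles", "")
            mol = Chem.MolFromSmiles(smi) if smi else None
            if mol is None:
                writer.writerow([smi, "", "unparseable SMILES"])
            else:
                writer.writerow([smi, Chem.MolToInchiKey(mol), ""])


def run_manifest(outp):
    from rdkit import rdBase
    names, groups = descriptor_names()
    manifest = {
        "engine": "rdkit",
        "engine_version": rdBase.rdkitVersion,
        "n_descriptors": len(names),
        "descriptors": [{"name": n, "group": g} for n, g in zip(names, groups)],
    }
    with open(outp, "w") as fo:
        json.dump(manifest, fo, indent=1)


if __name__ == "__main__":
    mode = sys.argv[1]
    if mode == "descriptors":
        run_descriptors(sys.argv[2], sys.argv[3])
    elif mode == "inchikey":
        run_inchikey(sys.argv[2], sys.argv[3])
    elif mode == "manifest":
        run_manifest(sys.argv[2])
    else:
        raise SystemExit("unknown mode: " + mode)
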