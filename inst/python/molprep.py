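"""Molecular preparation backend for the quinsar R package.

Reads a tab-separated SMILES file (SMILES<TAB>id per line) or an SDF file and
writes one JSON document describing each molecule: connectivity, optional
embedded 3-D coordinates (seeded ETKDG + UFF minimization), Gasteiger partial
charges, Wildman-Crippen per-atom logP contributions, and Lipinski-style
hydrogen-bond donor/acceptor atom flags.

Everything here is deterministic for a fixed --seed: ETKDG is seeded, UFF
minimization is a deterministic local optimizer, and charge/contribution
models are closed-form.

Usage:
    python molprep.py --in mols.smi --out mols.json [--seed 1] [--no3d]
                      [--format smi|sdf] [--attempts 10]
"""

import argparse
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Lipinski, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")


def atom_flags(mol):
    """Hydrogen-bond donor/acceptor flags per atom (RDKit Lipinski SMARTS)."""
    don = {i for (i,) in mol.GetSubstructMatches(Lipinski.HDonorSmarts)}
    acc = {i for (i,) in mol.GetSubstructMatches(Lipinski.HAcceptorSmarts)}
    return don, acc


def describe(mol, mid, seed, embed, attempts):
    rec = {"id": mid}
    mol = Chem.AddHs(mol)
    e_pre = e_post = None
    if embed:
        cid = -1
        for k in range(attempts):
            params = AllChem.ETKDGv3()
            params.randomSeed = (seed + k) % 2147483647
            cid = AllChem.EmbedMolecule(mol, params)
            if cid >= 0:
                break
        if cid < 0:
            rec["error"] = "embedding failed after %d attempts" % attempts
            return rec
        ff = AllChem.UFFGetMoleculeForceField(mol)
        e_pre = ff.CalcEnergy()
        AllChem.UFFOptimizeMolecule(mol, maxIters=2000)
        e_post = AllChem.UFFGetMoleculeForceField(mol).CalcEnergy()
    AllChem.ComputeGasteigerCharges(mol)
    crippen = rdMolDescriptors._CalcCrippenContribs(mol)
    don, acc = atom_flags(mol)
    conf = mol.GetConformer() if embed else None
    atoms = []
    for a in mol.GetAtoms():
        i = a.GetIdx()
        q = float(a.GetProp("_GasteigerCharge"))
        if q != q:  # NaN guard for exotic atoms
            q = 0.0
        if conf is not None:
            p = conf.GetAtomPosition(i)
            xyz = [p.x, p.y, p.z]
        else:
            xyz = [None, None, None]
        atoms.append(
            {
                "element": a.GetSymbol(),
                "x": xyz[0],
                "y": xyz[1],
                "z": xyz[2],
                "charge": q,
                "hydro": crippen[i][0],
                "hbd": i in don,
                "hba": i in acc,
                "formal": a.GetFormalCharge(),
            }
        )
    bonds = [
        {
            "a1": b.GetBeginAtomIdx() + 1,
            "a2": b.GetEndAtomIdx() + 1,
            "order": b.GetBondTypeAsDouble(),
        }
        for b in mol.GetBonds()
    ]
    rec.update(
        {
            "atoms": atoms,
            "bonds": bonds,
            "netCharge": Chem.GetFormalCharge(mol),
            "formula": rdMolDescriptors.CalcMolFormula(mol),
            "canonicalSmiles": Chem.MolToSmiles(Chem.RemoveHs(mol)),
            "ePre": e_pre,
            "ePost": e_post,
        }
    )
    return rec


def read_inputs(path, fmt):
    if fmt == "sdf":
        supp = Chem.SDMolSupplier(path, removeHs=True, sanitize=True)
        for k, mol in enumerate(supp):
            mid = None
            if mol is not None:
                mid = mol.GetProp("_Name") if mol.HasProp("_Name") else None
            yield mol, (mid or "mol%d" % (k + 1))
    else:
        with open(path) as fh:
            for k, line in enumerate(fh):
                line = line.rstrip("\n")
                if not line.strip():
                    continue
                parts = line.split("\t")
                smi = parts[0].strip()
                mid = parts[1].strip() if len(parts) > 1 else "mol%d" % (k + 1)
                yield Chem.MolFromSmiles(smi), mid


def main(argv=None):
    ap = argparse.ArgumentParser()
    ap.add_argument("--in", dest="infile", required=True)
    ap.add_argument("--out", dest="outfile", required=True)
    ap.add_argument("--seed", type=int, default=1)
    ap.add_argument("--format", choices=["smi", "sdf"], default="smi")
    ap.add_argument("--no3d", action="store_true")
    ap.add_argument("--attempts", type=int, default=10)
    args = ap.parse_args(argv)

    out = []
    for mol, mid in read_inputs(args.infile, args.format):
        if mol is None:
            out.append({"id": mid, "error": "unparsable record"})
            continue
        out.append(describe(mol, mid, args.seed, not args.no3d, args.attempts))
    with open(args.outfile, "w") as fh:
        json.dump(out, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main())
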