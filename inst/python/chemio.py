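"""Batched molecule I/O helper.

Reads one JSON request on stdin, writes one JSON response on stdout.
Backed by RDKit. Every operation is deterministic: conformer embedding uses
ETKDG with an explicit random seed.

Requests:
  {"op": "parse_smiles", "smiles": [...], "seed": 7}
  {"op": "parse_sdf", "sdf": "...molblocks..."}
  {"op": "canon_from_sdf", "sdf": "...molblocks..."}

parse_* responses carry, per molecule: canonical (isomeric canonical SMILES),
elements, formal_charges, bonds [[i, j, order], ...] (1-based), aromatic
flags, coords (n x 3, Angstrom), gasteiger charges. parse_smiles rebuilds
each molecule from its canonical SMILES first, so atom order is canonical.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")

BOND_ORDER = {
    Chem.BondType.SINGLE: 1,
    Chem.BondType.DOUBLE: 2,
    Chem.BondType.TRIPLE: 3,
    Chem.BondType.AROMATIC: 4,
}


def mol_payload(mol, embed_seed=None):
    """Serialize a molecule with explicit hydrogens and one conformer."""
    mol = Chem.AddHs(mol, addCoords=mol.GetNumConformers() > 0)
    if embed_seed is not None:
        params = AllChem.ETKDGv3()
        params.randomSeed = int(embed_seed)
        if AllChem.EmbedMolecule(mol, params) != 0:
            # retry with random coordinate initialization before giving up
            params.useRandomCoords = True
            if AllChem.EmbedMolecule(mol, params) != 0:
                return {"error": "3-D embedding failed"}
        AllChem.MMFFOptimizeMolecule(mol, maxIters=500)
    if mol.GetNumConformers() == 0:
        return {"error": "no conformer available"}
    AllChem.ComputeGasteigerCharges(mol)
    conf = mol.GetConformer(0)
    coords = [[conf.GetAtomPosition(i).x, conf.GetAtomPosition(i).y,
               conf.GetAtomPosition(i).z] for i in range(mol.GetNumAtoms())]
    charges = []
    for a in mol.GetAtoms():
        q = a.GetDoubleProp("_GasteigerCharge")
        q += a.GetDoubleProp("_GasteigerHCharge") if a.HasProp("_GasteigerHCharge") else 0.0
        charges.append(q if q == q else 0.0)  # NaN guard
    return {
        "canonical": Chem.MolToSmiles(Chem.RemoveHs(Chem.Mol(mol))),
        "elements": [a.GetSymbol() for a in mol.GetAtoms()],
        "formal_charges": [a.GetFormalCharge() for a in mol.GetAtoms()],
        "aromatic": [a.GetIsAromatic() for a in mol.GetAtoms()],
        "bonds": [[b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1,
                   BOND_ORDER.get(b.GetBondType(), 1)]
                  for b in mol.GetBonds()],
        "stereo_bonds": [[b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1]
                         for b in mol.GetBonds()
                         if b.GetStereo() != Chem.BondStereo.STEREONONE],
        "coords": coords,
        "charges": charges,
    }


def parse_smiles(req):
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"error": "invalid SMILES", "input": smi})
            continue
        canonical = Chem.MolToSmiles(mol)
        # rebuild from canonical form: canonical atom ordering
        mol = Chem.MolFromSmiles(canonical)
        payload = mol_payload(mol, embed_seed=req.get("seed", 7))
        payload["canonical"] = canonical
        out.append(payload)
    return out


def iter_molblocks(text):
    block = []
    for line in text.split("\n"):
        if line.startswith("$$$$"):
            yield "\n".join(block) + "\n"
            block = []
        else:
            block.append(line)
    if any(l.strip() for l in block):
        yield "\n".join(block) + "\n"


def parse_sdf(req):
    out = []
    for mb in iter_molblocks(req["sdf"]):
        mol = Chem.MolFromMolBlock(mb, removeHs=False)
        if mol is None:
            out.append({"error": "invalid molblock"})
            continue
        Chem.AssignStereochemistryFrom3D(mol)
        payload = mol_payload(mol)
        payload["canonical"] = Chem.MolToSmiles(Chem.RemoveHs(Chem.Mol(mol)))
        out.append(payload)
    return out


def canon_from_sdf(req):
    out = []
    for mb in iter_molblocks(req["sdf"]):
        mol = Chem.MolFromMolBlock(mb, removeHs=False)
        if mol is None:
            out.append({"error": "invalid molblock"})
            continue
        Chem.AssignStereochemistryFrom3D(mol)
        out.append({"canonical": Chem.MolToSmiles(Chem.RemoveHs(mol))})
    return out


OPS = {"parse_smiles": parse_smiles, "parse_sdf": parse_sdf,
       "canon_from_sdf": canon_from_sdf}


def main():
    req = json.load(sys.stdin)
    op = req.get("op")
    if op not in OPS:
        json.dump({"error": f"unknown op {op!r}"}, sys.stdout)
        return 2
    json.dump({"result": OPS[op](req)}, sys.stdout)
    return 0


if __name__ == "__main__":
    sys.exit(main())
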