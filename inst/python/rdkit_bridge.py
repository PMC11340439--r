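"""JSON subprocess bridge to RDKit.

Reads one JSON request from stdin, writes one JSON response to stdout.
Used by the R package for SMILES parsing and for ETKDGv3 conformer
embedding with MMFF94 energies. Heavy-atom order is RDKit's parse order
of the input SMILES; AddHs appends hydrogens after the heavy atoms, so
heavy-atom indices are stable between parsing and embedding.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")

BOND_CATEGORY = {
    Chem.BondType.SINGLE: "single",
    Chem.BondType.DOUBLE: "double",
}


def parse_one(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return {"error": "unparsable SMILES: %s" % smiles}
    atoms = []
    for atom in mol.GetAtoms():
        atoms.append({
            "element": atom.GetSymbol(),
            "attached_h_count": atom.GetTotalNumHs(),
        })
    bonds = []
    for bond in mol.GetBonds():
        cat = BOND_CATEGORY.get(bond.GetBondType(), "other")
        bonds.append({
            "i": bond.GetBeginAtomIdx(),
            "j": bond.GetEndAtomIdx(),
            "category": cat,
        })
    return {"atoms": atoms, "bonds": bonds,
            "canonical_smiles": Chem.MolToSmiles(mol)}


def embed_one(smiles, n_confs, seed):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return {"error": "unparsable SMILES: %s" % smiles}
    n_heavy = mol.GetNumAtoms()
    molh = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = int(seed)
    params.numThreads = 1
    conf_ids = AllChem.EmbedMultipleConfs(molh, numConfs=int(n_confs),
                                          params=params)
    if len(conf_ids) == 0:
        return {"error": "3D embedding failed for: %s" % smiles}
    props = AllChem.MMFFGetMoleculeProperties(molh)
    if props is None:
        return {"error": "MMFF94 setup failed for: %s" % smiles}
    coords, energies = [], []
    for cid in conf_ids:
        ff = AllChem.MMFFGetMoleculeForceField(molh, props, confId=cid)
        if ff is None:
            return {"error": "MMFF94 setup failed for: %s" % smiles}
        energies.append(ff.CalcEnergy())
        pos = molh.GetConformer(cid).GetPositions()
        coords.append([[round(v, 6) for v in pos[i]]
                       for i in range(n_heavy)])
    return {"n_heavy": n_heavy, "coords": coords, "energies": energies}


def main():
    req = json.load(sys.stdin)
    op = req["op"]
    if op == "parse":
        out = {"results": [parse_one(s) for s in req["smiles"]]}
    elif op == "embed":
        out = {"results": [embed_one(m["smiles"], req["n_confs"], m["seed"])
                           for m in req["molecules"]]}
    elif op == "ping":
        out = {"results": "pong"}
    else:
        out = {"error": "unknown op: %s" % op}
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
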