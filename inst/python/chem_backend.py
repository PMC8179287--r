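"""Batched RDKit helper for the regiosel R package.

Reads one JSON request from stdin, writes one JSON response to stdout.
Request: {"op": <name>, ...op-specific fields...}.  Every op is batched so a
single interpreter start-up serves many molecules/reactions.  All errors are
reported per-item; the process exits non-zero only on malformed requests.
"""

import json
import sys
from itertools import permutations

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

BOND_TYPE = {
    Chem.BondType.SINGLE: "single",
    Chem.BondType.DOUBLE: "double",
    Chem.BondType.TRIPLE: "triple",
    Chem.BondType.AROMATIC: "aromatic",
}


def strip_maps(mol):
    m = Chem.Mol(mol)
    for a in m.GetAtoms():
        a.SetAtomMapNum(0)
    return m


def canonical_smiles(mol):
    return Chem.MolToSmiles(strip_maps(mol))


def parse_one(smi):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return {"ok": False, "error": "parse", "message": "invalid SMILES: %s" % smi}
    maps = [a.GetAtomMapNum() for a in mol.GetAtoms() if a.GetAtomMapNum() > 0]
    if len(maps) != len(set(maps)):
        return {"ok": False, "error": "mapping",
                "message": "duplicated atom-map numbers in: %s" % smi}
    plain = strip_maps(mol)
    can = Chem.MolToSmiles(plain)
    # output order: canonical position k holds input atom order[k]
    order = json.loads(plain.GetProp("_smilesAtomOutputOrder")) \
        if plain.HasProp("_smilesAtomOutputOrder") else list(range(mol.GetNumAtoms()))
    atoms = []
    for a in mol.GetAtoms():
        atoms.append({
            "symbol": a.GetSymbol(),
            "atomic_num": a.GetAtomicNum(),
            "map_number": a.GetAtomMapNum(),
            "degree": a.GetDegree(),
            "valence": a.GetTotalValence(),
            "aromatic": bool(a.GetIsAromatic()),
            "num_h": a.GetTotalNumHs(),
            "formal_charge": a.GetFormalCharge(),
            "in_ring": a.IsInRing(),
        })
    bonds = []
    for b in mol.GetBonds():
        bonds.append({
            "i": b.GetBeginAtomIdx(),
            "j": b.GetEndAtomIdx(),
            "bond_type": BOND_TYPE.get(b.GetBondType(), "single"),
            "in_ring": b.IsInRing(),
        })
    return {
        "ok": True,
        "canonical": can,
        "canonical_order": list(order),
        "net_formal_charge": sum(a.GetFormalCharge() for a in mol.GetAtoms()),
        "atoms": atoms,
        "bonds": bonds,
    }


def op_parse(req):
    return [parse_one(s) for s in req["smiles"]]


def op_canonical(req):
    out = []
    for s in req["smiles"]:
        mol = Chem.MolFromSmiles(s)
        out.append(None if mol is None else canonical_smiles(mol))
    return out


def op_map_smiles(req):
    """Canonicalize, then write SMILES with map numbers 1..n (+offset) assigned
    in canonical atom order, so map k <-> canonical storage position k."""
    offset = int(req.get("offset", 0))
    out = []
    for s in req["smiles"]:
        mol = Chem.MolFromSmiles(s)
        if mol is None:
            out.append(None)
            continue
        can = canonical_smiles(mol)
        cmol = Chem.MolFromSmiles(can)
        for k, a in enumerate(cmol.GetAtoms()):
            a.SetAtomMapNum(offset + k + 1)
        out.append(Chem.MolToSmiles(cmol))
    return out


def _mapped_dict(mol):
    return {a.GetAtomMapNum(): a.GetIdx() for a in mol.GetAtoms()
            if a.GetAtomMapNum() > 0}


def _nbr_sig(mol, idx):
    """Multiset of (neighbor map, bond type) over mapped neighbors."""
    sig = []
    a = mol.GetAtomWithIdx(idx)
    for b in a.GetBonds():
        o = b.GetOtherAtom(a)
        if o.GetAtomMapNum() > 0:
            sig.append((o.GetAtomMapNum(), str(b.GetBondType())))
    return sorted(sig)


def extract_template_one(rxn_smi, radius):
    parts = rxn_smi.split(">")
    if len(parts) != 3:
        return {"ok": False, "error": "parse",
                "message": "expected reactants>reagents>products"}
    rsmi, _, psmi = parts
    rmol = Chem.MolFromSmiles(rsmi)
    pmol = Chem.MolFromSmiles(psmi)
    if rmol is None or pmol is None:
        return {"ok": False, "error": "parse", "message": "invalid reaction SMILES"}
    for a in pmol.GetAtoms():
        if a.GetAtomMapNum() == 0:
            return {"ok": False, "error": "UnmappedProductAtom",
                    "message": "product atom %s has no map number" % a.GetSymbol()}
    rmap, pmap = _mapped_dict(rmol), _mapped_dict(pmol)

    changed = set()
    for m, pidx in pmap.items():
        if m not in rmap:
            changed.add(m)
            continue
        ridx = rmap[m]
        if _nbr_sig(rmol, ridx) != _nbr_sig(pmol, pidx):
            changed.add(m)
        elif rmol.GetAtomWithIdx(ridx).GetTotalNumHs() != \
                pmol.GetAtomWithIdx(pidx).GetTotalNumHs():
            changed.add(m)
    # reactant bonds that break (partner vanishes or bond lost)
    for b in rmol.GetBonds():
        m1 = b.GetBeginAtom().GetAtomMapNum()
        m2 = b.GetEndAtom().GetAtomMapNum()
        if m1 == 0 or m2 == 0:
            continue
        if m1 in pmap and m2 in pmap:
            if pmol.GetBondBetweenAtoms(pmap[m1], pmap[m2]) is None:
                changed.update((m1, m2))
        elif (m1 in pmap) != (m2 in pmap):
            changed.update((m1, m2))
    changed_r = {m for m in changed if m in rmap}
    if not changed_r:
        return {"ok": False, "error": "NoChangeDetected",
                "message": "reactants and product have identical mapped environments"}

    # grow by bond radius on the reactant side
    r_atoms = {rmap[m] for m in changed_r}
    frontier = set(r_atoms)
    for _ in range(radius):
        nxt = set()
        for idx in frontier:
            for o in rmol.GetAtomWithIdx(idx).GetNeighbors():
                if o.GetIdx() not in r_atoms:
                    nxt.add(o.GetIdx())
        r_atoms |= nxt
        frontier = nxt
    r_maps = {rmol.GetAtomWithIdx(i).GetAtomMapNum() for i in r_atoms}
    p_atoms = {pmap[m] for m in r_maps if m in pmap}

    def side_frags(mol, atom_set):
        frags = []
        for comp in Chem.GetMolFrags(mol):
            sel = [i for i in comp if i in atom_set]
            if sel:
                frags.append(Chem.MolFragmentToSmiles(
                    mol, atomsToUse=sel, allHsExplicit=True, canonical=True))
        return frags

    smarts = ".".join(side_frags(rmol, r_atoms)) + ">>" + \
        ".".join(side_frags(pmol, p_atoms))

    # new bonds (product-side bonds absent between the same maps on reactant side)
    new_bonds = []
    for b in pmol.GetBonds():
        m1 = b.GetBeginAtom().GetAtomMapNum()
        m2 = b.GetEndAtom().GetAtomMapNum()
        if m1 in r_maps and m2 in r_maps:
            if m1 not in rmap or m2 not in rmap or \
                    rmol.GetBondBetweenAtoms(rmap.get(m1, 0), rmap.get(m2, 0)) is None:
                new_bonds.append(sorted((m1, m2)))
    return {"ok": True, "smarts": smarts, "radius": radius,
            "changed_maps": sorted(changed_r),
            "new_bond_maps": sorted(new_bonds)}


def op_extract_template(req):
    radius = int(req.get("radius", 1))
    return [extract_template_one(r, radius) for r in req["rxns"]]


def _template_map_owner(rxn):
    """template map number -> index of the reactant template holding it."""
    owner = {}
    for t, tmpl in enumerate(rxn.GetReactants()):
        for a in tmpl.GetAtoms():
            if a.GetAtomMapNum() > 0:
                owner[a.GetAtomMapNum()] = t
    return owner


def apply_template_one(smarts, reactant_smi, pair_tmaps):
    rxn = AllChem.ReactionFromSmarts(smarts, useSmiles=True)
    if rxn is None:
        return {"ok": False, "error": "BadTemplate", "message": smarts}
    rxn.Initialize()
    nt = rxn.GetNumReactantTemplates()
    comps = [Chem.MolFromSmiles(s) for s in reactant_smi.split(".")]
    if any(c is None for c in comps):
        return {"ok": False, "error": "parse", "message": reactant_smi}
    owner = _template_map_owner(rxn)
    results = {}
    tuples = [t for t in permutations(range(len(comps)), nt)]
    for tup in tuples:
        mols = tuple(comps[i] for i in tup)
        try:
            prods = rxn.RunReactants(mols)
        except Exception:
            continue
        for prod_set in prods:
            for p in prod_set:
                try:
                    # restore original reactant map numbers on template-matched atoms
                    tmap2orig = {}
                    for a in p.GetAtoms():
                        if a.HasProp("old_mapno") and a.HasProp("react_atom_idx"):
                            tmap = a.GetIntProp("old_mapno")
                            t = owner.get(tmap)
                            if t is None:
                                continue
                            src = mols[t].GetAtomWithIdx(
                                a.GetIntProp("react_atom_idx"))
                            tmap2orig[tmap] = src.GetAtomMapNum()
                            a.SetAtomMapNum(src.GetAtomMapNum())
                    Chem.SanitizeMol(p)
                except Exception:
                    continue
                can = canonical_smiles(p)
                pair = None
                if pair_tmaps is not None and len(pair_tmaps) == 2:
                    pair = [tmap2orig.get(pair_tmaps[0], 0),
                            tmap2orig.get(pair_tmaps[1], 0)]
                key = can
                if key not in results:
                    results[key] = {"product": can,
                                    "product_mapped": Chem.MolToSmiles(p),
                                    "pair": pair}
    if not results:
        return {"ok": False, "error": "NoMatch",
                "message": "template does not apply to %s" % reactant_smi}
    ordered = [results[k] for k in sorted(results)]
    return {"ok": True, "outcomes": ordered}


def op_apply_template(req):
    smarts = req["smarts"]
    pair = req.get("pair_tmaps")
    return [apply_template_one(smarts, s, pair) for s in req["reactants"]]


def op_scaffold(req):
    out = []
    for s in req["smiles"]:
        mol = Chem.MolFromSmiles(s)
        if mol is None:
            out.append(None)
            continue
        try:
            sc = MurckoScaffold.GetScaffoldForMol(strip_maps(mol))
            if sc is None or sc.GetNumAtoms() == 0:
                out.append("")
                continue
            gen = MurckoScaffold.MakeScaffoldGeneric(sc)
            out.append(Chem.MolToSmiles(gen))
        except Exception:
            out.append(Chem.MolToSmiles(sc) if sc is not None else "")
    return out


def _morgan_counts(mol, radius, nbits):
    fp = AllChem.GetMorganFingerprint(mol, radius)
    dense = {}
    for h, c in fp.GetNonzeroElements().items():
        k = int(h % nbits)
        dense[k] = dense.get(k, 0) + c
    return dense


def op_reaction_fp(req):
    """Signed Morgan difference fingerprint: product counts - reactant counts,
    folded to nbits."""
    nbits = int(req.get("bits", 2048))
    radius = int(req.get("radius", 2))
    out = []
    for item in req["reactions"]:
        rmol = Chem.MolFromSmiles(item["reactants"])
        pmol = Chem.MolFromSmiles(item["product"])
        if rmol is None or pmol is None:
            out.append({"ok": False, "error": "parse"})
            continue
        diff = _morgan_counts(strip_maps(pmol), radius, nbits)
        for k, c in _morgan_counts(strip_maps(rmol), radius, nbits).items():
            diff[k] = diff.get(k, 0) - c
        idx = sorted(k for k in diff if diff[k] != 0)
        out.append({"ok": True,
                    "idx": idx,
                    "val": [diff[k] for k in idx]})
    return out


OPS = {
    "parse": op_parse,
    "canonical": op_canonical,
    "map_smiles": op_map_smiles,
    "extract_template": op_extract_template,
    "apply_template": op_apply_template,
    "scaffold": op_scaffold,
    "reaction_fp": op_reaction_fp,
}


def main():
    req = json.load(sys.stdin)
    op = req.get("op")
    if op not in OPS:
        sys.stderr.write("unknown op: %r\n" % op)
        sys.exit(2)
    json.dump(OPS[op](req), sys.stdout)


if __name__ == "__main__":
    main()
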