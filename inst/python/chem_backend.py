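"""Batched RDKit worker for the ckifrags R package.

Invoked as:  python chem_backend.py <op> <infile.json> <outfile.json>

Every operation reads one JSON payload and writes one JSON payload, so a
single process handles an arbitrary batch of molecules.  All outputs are
plain lists (no dict-order dependence) and RDKit canonicalisation is the
only source of atom ordering, which keeps reruns byte-identical.
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Crippen, Descriptors, Lipinski, Recap

RDLogger.DisableLog("rdApp.*")

MAX_PLACEMENTS = 32


def _mol(smiles):
    return Chem.MolFromSmiles(smiles)


def _largest_organic(mol):
    """Largest fragment by heavy-atom count; prefer carbon-bearing pieces,
    break remaining ties on canonical SMILES so desalting is deterministic."""
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=True)
    if len(frags) == 1:
        return frags[0]

    def key(f):
        has_c = any(a.GetAtomicNum() == 6 for a in f.GetAtoms())
        return (-int(has_c), -f.GetNumHeavyAtoms(), Chem.MolToSmiles(f))

    return sorted(frags, key=key)[0]


def op_version(payload):
    import rdkit

    return {"rdkit": rdkit.__version__}


def op_canonical(payload):
    desalt = payload.get("desalt", True)
    out = []
    for smi in payload["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append({"ok": False, "error": "unparseable SMILES"})
            continue
        if desalt:
            m = _largest_organic(m)
        out.append(
            {
                "ok": True,
                "canonical": Chem.MolToSmiles(m),
                "n_heavy": m.GetNumHeavyAtoms(),
            }
        )
    return {"results": out}


def _raw_matches(mol, patterns):
    """All substructure placements of every pattern, uniquified by atom set."""
    found = []
    for pat in patterns:
        q = Chem.MolFromSmarts(pat["smarts"])
        if q is None:
            raise ValueError("invalid SMARTS for id %s" % pat["id"])
        seen = set()
        for match in mol.GetSubstructMatches(q, uniquify=True, maxMatches=256):
            atoms = frozenset(match)
            if atoms in seen:
                continue
            seen.add(atoms)
            attach = set()
            for idx in atoms:
                for nb in mol.GetAtomWithIdx(idx).GetNeighbors():
                    if nb.GetIdx() not in atoms:
                        attach.add(nb.GetIdx())
            found.append(
                {
                    "id": pat["id"],
                    "atoms": sorted(atoms),
                    "attachments": sorted(attach),
                }
            )
    return found


def op_parse_smarts(payload):
    out = []
    for pat in payload["patterns"]:
        q = Chem.MolFromSmarts(pat["smarts"])
        if q is None:
            out.append({"id": pat["id"], "ok": False})
        else:
            out.append({"id": pat["id"], "ok": True, "n_atoms": q.GetNumAtoms()})
    return {"results": out}


def op_match(payload):
    patterns = payload["patterns"]
    out = []
    for smi in payload["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append({"ok": False, "error": "unparseable SMILES"})
            continue
        out.append({"ok": True, "matches": _raw_matches(m, patterns)})
    return {"results": out}


def _clean_smiles(frag_mol):
    """Hydrogen-cap the dummy attachment points and canonicalise."""
    rw = Chem.RWMol(frag_mol)
    for atom in rw.GetAtoms():
        if atom.GetAtomicNum() == 0:
            atom.SetAtomicNum(1)
            atom.SetIsotope(0)
    m = rw.GetMol()
    try:
        Chem.SanitizeMol(m)
        m = Chem.RemoveHs(m)
    except Exception:
        return None
    return Chem.MolToSmiles(m)


def _leaf_placements(root, leaf_mol):
    """Embed a dummy-marked leaf back into its root molecule; dummies act
    as wildcards.  Returns per-placement covered/real root atom indices."""
    qp = Chem.AdjustQueryParameters.NoAdjustments()
    qp.makeDummiesQueries = True
    q = Chem.AdjustQueryProperties(leaf_mol, qp)
    dummy_q = {a.GetIdx() for a in leaf_mol.GetAtoms() if a.GetAtomicNum() == 0}
    placements = []
    for match in root.GetSubstructMatches(q, uniquify=True, maxMatches=MAX_PLACEMENTS):
        covered = sorted(match)
        real = sorted(
            idx for qi, idx in enumerate(match) if qi not in dummy_q
        )
        placements.append({"covered": covered, "real": real})
    return placements


def _serialize_recap(root_mol, tree):
    nodes = []

    def walk(node, parent_id, depth):
        node_id = len(nodes)
        leaf = not node.children
        frag = node.mol if node.mol is not None else _mol(node.smiles)
        n_dummies = sum(1 for a in frag.GetAtoms() if a.GetAtomicNum() == 0)
        rec = {
            "node_id": node_id,
            "parent_id": parent_id,
            "depth": depth,
            "smiles": node.smiles,
            "is_leaf": leaf,
            "n_dummies": n_dummies,
            "n_heavy": frag.GetNumHeavyAtoms() - n_dummies,
            "clean": _clean_smiles(frag),
        }
        if leaf and depth > 0:
            rec["placements"] = _leaf_placements(root_mol, frag)
        nodes.append(rec)
        for smi in sorted(node.children):
            walk(node.children[smi], node_id, depth + 1)

    walk(tree, None, 0)
    return nodes


def op_recap(payload):
    out = []
    for smi in payload["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append({"ok": False, "error": "unparseable SMILES"})
            continue
        tree = Recap.RecapDecompose(m)
        out.append({"ok": True, "nodes": _serialize_recap(m, tree)})
    return {"results": out}


def op_descriptors(payload):
    out = []
    for smi in payload["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append({"ok": False, "error": "unparseable SMILES"})
            continue
        out.append(
            {
                "ok": True,
                "MW": Descriptors.MolWt(m),
                "logP": Crippen.MolLogP(m),
                "HBA": Lipinski.NumHAcceptors(m),
                "HBD": Lipinski.NumHDonors(m),
            }
        )
    return {"results": out}


def op_morgan(payload):
    radius = payload.get("radius", 2)
    n_bits = payload.get("n_bits", 2048)
    gen = AllChem.GetMorganGenerator(radius=radius, fpSize=n_bits)
    out = []
    for smi in payload["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append({"ok": False, "error": "unparseable SMILES"})
            continue
        fp = gen.GetFingerprint(m)
        out.append({"ok": True, "bits": sorted(fp.GetOnBits())})
    return {"results": out}


def op_substruct(payload):
    out = []
    for pair in payload["pairs"]:
        t = _mol(pair["target"])
        q = _mol(pair["query"])
        if t is None or q is None:
            out.append({"ok": False})
            continue
        out.append({"ok": True, "found": t.HasSubstructMatch(q)})
    return {"results": out}


def _fallback_candidates(mol, matches):
    """Cut the warhead out along acyclic single bonds and Recap the
    remainder; a candidate bridges the cut point and one further Recap
    attachment.  Pattern atoms sitting inside rings are treated as
    scaffold-side anchors, so the cut happens between the electrophilic
    core and the ring system (covers e.g. aryl aldehydes)."""
    cands = []
    for match in matches:
        atoms = set(match["atoms"])
        cut_bonds = []
        for idx in atoms:
            a = mol.GetAtomWithIdx(idx)
            if a.IsInRing():
                continue
            for nb in a.GetNeighbors():
                j = nb.GetIdx()
                external = j not in atoms
                ring_anchor = j in atoms and nb.IsInRing()
                if not (external or ring_anchor):
                    continue
                bond = mol.GetBondBetweenAtoms(idx, j)
                if bond.GetBondType() != Chem.BondType.SINGLE or bond.IsInRing():
                    continue
                cut_bonds.append(bond.GetIdx())
        cut_bonds = sorted(set(cut_bonds))
        if not cut_bonds:
            continue
        pieces = Chem.FragmentOnBonds(mol, cut_bonds, addDummies=True)
        for piece in Chem.GetMolFrags(pieces, asMols=True, sanitizeFrags=False):
            try:
                Chem.SanitizeMol(piece)
            except Exception:
                continue
            # skip the warhead piece itself: it is mostly match atoms
            real = [a for a in piece.GetAtoms() if a.GetAtomicNum() != 0]
            if len(real) <= len(atoms):
                warhead_side = True
            else:
                warhead_side = False
            if warhead_side:
                continue
            remainder = Chem.MolToSmiles(piece)
            rem = _mol(remainder)
            if rem is None:
                continue
            cut_dummies = {
                a.GetIdx() for a in rem.GetAtoms() if a.GetAtomicNum() == 0
            }
            tree = Recap.RecapDecompose(rem)
            leaves = tree.GetLeaves()
            if not leaves:
                continue
            for smi in sorted(leaves):
                leaf = leaves[smi].mol or _mol(smi)
                nd = sum(1 for a in leaf.GetAtoms() if a.GetAtomicNum() == 0)
                if nd < 2:
                    continue
                for pl in _leaf_placements(rem, leaf):
                    covered = set(pl["covered"])
                    if covered & cut_dummies:
                        clean = _clean_smiles(leaf)
                        if clean is not None:
                            cands.append(
                                {
                                    "warhead_id": match["id"],
                                    "marked": Chem.MolToSmiles(leaf),
                                    "clean": clean,
                                    "n_attach": nd,
                                }
                            )
                        break
    return cands


def op_fallback(payload):
    out = []
    for rec in payload["molecules"]:
        m = _mol(rec["smiles"])
        if m is None:
            out.append({"ok": False, "error": "unparseable SMILES"})
            continue
        out.append({"ok": True, "candidates": _fallback_candidates(m, rec["matches"])})
    return {"results": out}


OPS = {
    "version": op_version,
    "canonical": op_canonical,
    "parse_smarts": op_parse_smarts,
    "match": op_match,
    "recap": op_recap,
    "descriptors": op_descriptors,
    "morgan": op_morgan,
    "substruct": op_substruct,
    "fallback": op_fallback,
}


def main(argv):
    if len(argv) != 4:
        sys.stderr.write("usage: chem_backend.py <op> <in.json> <out.json>\n")
        return 2
    op, infile, outfile = argv[1], argv[2], argv[3]
    if op not in OPS:
        sys.stderr.write("unknown op: %s\n" % op)
        return 2
    with open(infile) as fh:
        payload = json.load(fh)
    result = OPS[op](payload)
    with open(outfile, "w") as fh:
        json.dump(result, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
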