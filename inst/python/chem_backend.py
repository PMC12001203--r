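"""Chemistry backend for the crmscreen R package.

Reads one JSON request from stdin and writes one JSON response to stdout.
All structure-level chemistry (SMILES parsing/canonicalization, reaction-SMARTS
application, Morgan fingerprints) is delegated to RDKit; the R side owns mass
bookkeeping, enumeration order and provenance.

Request forms:
  {"op": "canon",  "smiles": [...]}
  {"op": "react",  "rxn": "<reaction SMARTS>", "pairs": [[s1, s2], ...]}
  {"op": "morgan", "smiles": [...], "radius": 2, "nbits": 2048}
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")


def canon(req):
    out = []
    for s in req["smiles"]:
        ok_input = isinstance(s, str) and s.strip() != ""
        m = Chem.MolFromSmiles(s) if ok_input else None
        if m is None:
            out.append({"ok": False, "smiles": None, "formula": None})
        else:
            out.append({
                "ok": True,
                "smiles": Chem.MolToSmiles(m),
                "formula": rdMolDescriptors.CalcMolFormula(m),
            })
    return {"results": out}


def react(req):
    rxn = AllChem.ReactionFromSmarts(req["rxn"])
    if rxn is None:
        raise ValueError("invalid reaction SMARTS: %s" % req["rxn"])
    n_templates = rxn.GetNumReactantTemplates()
    out = []
    for pair in req["pairs"]:
        mols = [Chem.MolFromSmiles(s) for s in pair]
        if any(m is None for m in mols) or len(mols) != n_templates:
            out.append(None)
            continue
        try:
            prods = rxn.RunReactants(tuple(mols))
        except Exception:
            prods = ()
        smis = set()
        for p in prods:
            if len(p) != 1:
                continue
            m = p[0]
            try:
                Chem.SanitizeMol(m)
                smis.add(Chem.MolToSmiles(m))
            except Exception:
                continue
        # deterministic: distinct sanitized products, sorted
        out.append(sorted(smis) if smis else None)
    return {"results": out}


def morgan(req):
    radius = int(req.get("radius", 2))
    nbits = int(req.get("nbits", 2048))
    out = []
    for s in req["smiles"]:
        m = Chem.MolFromSmiles(s)
        if m is None:
            out.append(None)
            continue
        fp = AllChem.GetMorganFingerprintAsBitVect(m, radius, nBits=nbits)
        out.append(sorted(int(b) for b in fp.GetOnBits()))
    return {"results": out, "radius": radius, "nbits": nbits}


OPS = {"canon": canon, "react": react, "morgan": morgan}


def main():
    req = json.load(sys.stdin)
    op = req.get("op")
    if op not in OPS:
        raise ValueError("unknown op: %r" % op)
    json.dump(OPS[op](req), sys.stdout)


if __name__ == "__main__":
    main()
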