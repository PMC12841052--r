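"""Batch chemistry worker for the cddap R package.

Called as:  python worker.py <command> <request.json> <response.json>

Every command reads one JSON request, does a batch of work with RDKit
(and umap-learn for the embedding commands), and writes one JSON response.
Large arrays (fingerprints, coordinates) travel through sidecar text files
whose paths are given in the request, so the JSON stays small.

All randomness is controlled by seeds passed in the request.
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Crippen, Descriptors, QED
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")


# ---------------------------------------------------------------- helpers

def _mol(smi):
    if smi is None:
        return None
    return Chem.MolFromSmiles(smi)


def _canon(mol):
    return Chem.MolToSmiles(mol)


def cmd_canon(req):
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        out.append(_canon(m) if m is not None else None)
    return {"smiles": out}


_UNCHARGER = rdMolStandardize.Uncharger()


def cmd_desalt(req):
    """Largest covalent fragment by heavy atoms; ties broken by canonical
    SMILES sort order; simple protonation-state neutralisation."""
    smiles, ok, reason = [], [], []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            smiles.append(None)
            ok.append(False)
            reason.append("parse_error")
            continue
        frags = Chem.GetMolFrags(m, asMols=True, sanitizeFrags=False)
        best = None
        for f in frags:
            try:
                Chem.SanitizeMol(f)
            except Exception:
                continue
            key = (-f.GetNumHeavyAtoms(), _canon(f))
            if best is None or key < best[0]:
                best = (key, f)
        if best is None:
            smiles.append(None)
            ok.append(False)
            reason.append("sanitize_error")
            continue
        f = _UNCHARGER.uncharge(best[1])
        smiles.append(_canon(f))
        ok.append(True)
        reason.append("")
    return {"smiles": smiles, "ok": ok, "reason": reason}


def cmd_match(req):
    """Substructure match counts: one row per SMILES, one column per SMARTS."""
    patts = [Chem.MolFromSmarts(s) for s in req["smarts"]]
    if any(p is None for p in patts):
        raise ValueError("invalid SMARTS in request")
    counts, ok = [], []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            counts.append([-1] * len(patts))
            ok.append(False)
            continue
        counts.append([len(m.GetSubstructMatches(p)) for p in patts])
        ok.append(True)
    return {"counts": counts, "ok": ok}


def cmd_descriptors(req):
    """Average MW, monoisotopic mass, Crippen clogP, Lipinski HBD/HBA
    (NHOH / NO counts) and the eight raw QED descriptors, plus RDKit's own
    QED score (used by the R tests as an independent oracle)."""
    cols = {k: [] for k in (
        "mw", "exactmw", "clogp", "hbd", "hba",
        "qed_mw", "qed_alogp", "qed_hba", "qed_hbd", "qed_psa",
        "qed_rotb", "qed_arom", "qed_alerts", "qed_rdkit", "ok")}
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            for k in cols:
                cols[k].append(False if k == "ok" else None)
            continue
        props = QED.properties(m)
        cols["mw"].append(Descriptors.MolWt(m))
        cols["exactmw"].append(Descriptors.ExactMolWt(m))
        cols["clogp"].append(Crippen.MolLogP(m))
        cols["hbd"].append(Descriptors.NHOHCount(m))
        cols["hba"].append(Descriptors.NOCount(m))
        cols["qed_mw"].append(props.MW)
        cols["qed_alogp"].append(props.ALOGP)
        cols["qed_hba"].append(props.HBA)
        cols["qed_hbd"].append(props.HBD)
        cols["qed_psa"].append(props.PSA)
        cols["qed_rotb"].append(props.ROTB)
        cols["qed_arom"].append(props.AROM)
        cols["qed_alerts"].append(props.ALERTS)
        cols["qed_rdkit"].append(QED.qed(m))
        cols["ok"].append(True)
    return cols


def cmd_fingerprints(req):
    """Morgan or FCFP-style (feature Morgan) bit fingerprints, written as
    lines of '0'/'1' characters to req['out']."""
    nbits = int(req.get("nbits", 1024))
    radius = int(req.get("radius", 2))
    features = req.get("kind", "morgan") == "fcfp"
    gen = AllChem.GetMorganGenerator(radius=radius, fpSize=nbits)
    if features:
        inv = AllChem.GetMorganFeatureAtomInvGen()
        gen = AllChem.GetMorganGenerator(radius=radius, fpSize=nbits,
                                         atomInvariantsGenerator=inv)
    failed = []
    with open(req["out"], "w") as fh:
        for i, smi in enumerate(req["smiles"]):
            m = _mol(smi)
            if m is None:
                failed.append(i + 1)  # 1-based for R
                fh.write("\n")
                continue
            fh.write(gen.GetFingerprint(m).ToBitString() + "\n")
    return {"n": len(req["smiles"]), "failed": failed}


# ------------------------------------------------------------- transforms
#
# The four scheme steps, encoded as reaction SMARTS. Site selectivity
# mirrors the scaffold's reactivity hierarchy: the aromatic azide is always
# consumed by step 1, the benzylic azide by step 2.

RXN = {
    # aromatic azide + active methylene -> 1-aryl-1,4,5-trisubstituted
    # 1,2,3-triazole; ketone oxygen leaves as water.  Former methylene C
    # becomes C4 (keeps R3), former ketone C becomes C5 (keeps R2).
    "enolate_cycloaddition": AllChem.ReactionFromSmarts(
        "[c:1][N:2]=[N+:3]=[N-:4].[#6:7][CX3:5](=[OX1:6])[CH2X4:8][#6,#16:9]"
        ">>[c:1][N+0:2]1[N+0:3]=[N+0:4][C:8]([*:9])=[C:5]1[*:7]"),
    # aliphatic (benzylic) azide + terminal alkyne -> 1,4-triazole
    "cuaac": AllChem.ReactionFromSmarts(
        "[CX4:1][N:2]=[N+:3]=[N-:4].[CX2H1:5]#[CX2:6][#6:7]"
        ">>[C:1][N+0:2]1[N+0:3]=[N+0:4][C:6]([*:7])=[CH1:5]1"),
    "reduce_azide_aromatic": AllChem.ReactionFromSmarts(
        "[c:1][N:2]=[N+]=[N-]>>[c:1][NH2+0:2]"),
    "reduce_azide_aliphatic": AllChem.ReactionFromSmarts(
        "[CX4:1][N:2]=[N+]=[N-]>>[C:1][NH2+0:2]"),
    "amidate": AllChem.ReactionFromSmarts(
        "[NX3;H2:1].[CX3:2](=[OX1:3])[OX2H1]>>[N:1][C:2]=[O:3]"),
}

PAT_AROMATIC_AZIDE = Chem.MolFromSmarts("c[NX2]=[NX2+]=[NX1-]")
PAT_ALIPHATIC_AZIDE = Chem.MolFromSmarts("[CX4][NX2]=[NX2+]=[NX1-]")
PAT_ANY_AZIDE = Chem.MolFromSmarts("[NX2]=[NX2+]=[NX1-]")
PAT_TERMINAL_ALKYNE = Chem.MolFromSmarts("[CX2H1]#[CX2]")
PAT_COOH = Chem.MolFromSmarts("[CX3](=[OX1])[OX2H1]")
PAT_PRIMARY_AMINE = Chem.MolFromSmarts("[NX3H2;!$(NC=O)]")


def _run_unimolecular(name, mol):
    prods = RXN[name].RunReactants((mol,))
    return _best_product(prods)


def _best_product(prods):
    """Deterministic product choice: lexicographically smallest canonical
    SMILES among sanitizable products; also reports the number of distinct
    outcomes (for ambiguity flagging)."""
    seen = set()
    for tup in prods:
        p = tup[0]
        try:
            Chem.SanitizeMol(p)
        except Exception:
            continue
        seen.add(_canon(p))
    if not seen:
        return None, 0
    return min(seen), len(seen)


def apply_transform(op, structure, bb):
    """One scheme step on one (structure, bb) pair.
    Returns (smiles or None, reason)."""
    m = _mol(structure)
    if m is None:
        return None, "parse_error_structure"
    b = _mol(bb) if bb is not None else None

    if op == "enolate_cycloaddition":
        if b is None:
            return None, "parse_error_bb"
        if not m.HasSubstructMatch(PAT_AROMATIC_AZIDE):
            return None, "no_aromatic_azide"
        if not b.HasSubstructMatch(
                Chem.MolFromSmarts("[#6][CX3](=[OX1])[CH2X4]")):
            return None, "incompatible_bb"
        smi, n = _best_product(RXN[op].RunReactants((m, b)))
        if smi is None:
            return None, "incompatible_bb"
        return smi, ("ambiguous_site" if n > 1 else "")

    if op == "cuaac":
        if b is None:
            return None, "parse_error_bb"
        # reactivity hierarchy: the aromatic azide must already be consumed
        if m.HasSubstructMatch(PAT_AROMATIC_AZIDE):
            return None, "aromatic_azide_present"
        if len(b.GetSubstructMatches(PAT_TERMINAL_ALKYNE)) != 1:
            return None, "incompatible_bb"
        smi, n = _best_product(RXN[op].RunReactants((m, b)))
        if smi is None:
            return None, "incompatible_bb"
        return smi, ("ambiguous_site" if n > 1 else "")

    if op == "reduce_azide_aromatic":
        if not m.HasSubstructMatch(PAT_AROMATIC_AZIDE):
            return None, "no_aromatic_azide"
        smi, _ = _run_unimolecular(op, m)
        return smi, ""

    if op == "reduce_azide_aliphatic":
        if m.HasSubstructMatch(PAT_AROMATIC_AZIDE):
            return None, "aromatic_azide_present"
        if not m.HasSubstructMatch(PAT_ALIPHATIC_AZIDE):
            return None, "no_aliphatic_azide"
        smi, _ = _run_unimolecular(op, m)
        return smi, ""

    if op == "amidate":
        if b is None:
            return None, "parse_error_bb"
        if len(b.GetSubstructMatches(PAT_COOH)) != 1:
            return None, "ambiguous_bb"
        if not m.HasSubstructMatch(PAT_PRIMARY_AMINE):
            return None, "no_primary_amine"
        smi, n = _best_product(RXN["amidate"].RunReactants((m, b)))
        if smi is None:
            return None, "incompatible_bb"
        return smi, ("ambiguous_site" if n > 1 else "")

    if op == "reduce_amidate_aromatic":
        smi, reason = apply_transform("reduce_azide_aromatic", structure, None)
        if smi is None:
            return None, reason
        return apply_transform("amidate", smi, bb)

    if op == "reduce_amidate_aliphatic":
        smi, reason = apply_transform("reduce_azide_aliphatic", structure, None)
        if smi is None:
            return None, reason
        return apply_transform("amidate", smi, bb)

    raise ValueError("unknown transform: " + op)


def cmd_transform(req):
    op = req["op"]
    structures = req["structures"]
    bbs = req.get("bbs")
    out, reason = [], []
    for i, s in enumerate(structures):
        b = bbs[i] if bbs is not None else None
        smi, why = apply_transform(op, s, b)
        out.append(smi)
        reason.append(why)
    return {"smiles": out, "reason": reason}


def cmd_enumerate(req):
    """Full BB1-major enumeration of one scheme: step1 applied once per bb1,
    step2 applied to every (intermediate, bb2) pair.  Results stream to a
    CSV sidecar (i, j, smiles, mw, exactmw, reason)."""
    step1, step2 = req["steps"]
    scaffold = req["scaffold"]
    bb1, bb2 = req["bb1"], req["bb2"]
    n_ok = 0
    inter = []
    for s in bb1:
        smi, why = apply_transform(step1, scaffold, s)
        inter.append((smi, why))
    bb2_mols = [_mol(s) for s in bb2]
    with open(req["out"], "w") as fh:
        fh.write("i,j,smiles,mw,exactmw,reason\n")
        for i, (ismi, iwhy) in enumerate(inter):
            for j in range(len(bb2)):
                if ismi is None:
                    fh.write(f"{i + 1},{j + 1},,NA,NA,step1_{iwhy}\n")
                    continue
                smi, why = apply_transform(step2, ismi, bb2[j])
                if smi is None:
                    fh.write(f"{i + 1},{j + 1},,NA,NA,step2_{why}\n")
                    continue
                m = _mol(smi)
                fh.write(f"{i + 1},{j + 1},{smi},"
                         f"{Descriptors.MolWt(m):.4f},"
                         f"{Descriptors.ExactMolWt(m):.5f},{why}\n")
                n_ok += 1
    return {"n_pairs": len(bb1) * len(bb2), "n_ok": n_ok}


def cmd_sdf_write(req):
    w = Chem.SDWriter(req["out"])
    props = req.get("props", {})
    n = 0
    for i, smi in enumerate(req["smiles"]):
        m = _mol(smi)
        if m is None:
            continue
        for key, vals in props.items():
            m.SetProp(key, str(vals[i]))
        w.write(m)
        n += 1
    w.close()
    return {"n": n}


# ------------------------------------------------------------------ umap

def _read_fps(path):
    import numpy as np
    rows = []
    with open(path) as fh:
        for line in fh:
            line = line.strip()
            rows.append(np.frombuffer(line.encode(), dtype=np.uint8) - ord("0"))
    return np.vstack(rows)


def _write_coords(path, arr):
    with open(path, "w") as fh:
        fh.write("x,y\n")
        for row in arr:
            fh.write(f"{row[0]:.6f},{row[1]:.6f}\n")


def _fit_umap(fps_path, req):
    import warnings
    warnings.filterwarnings("ignore")
    import umap
    X = _read_fps(fps_path)
    nn = int(req.get("n_neighbors", 50))
    if X.shape[0] < nn:
        raise ValueError(
            f"n_neighbors ({nn}) exceeds the number of reference compounds "
            f"({X.shape[0]}); lower n_neighbors")
    # init="random" (seeded): the spectral default falls back to an
    # unseeded ARPACK solve when the neighbour graph is disconnected,
    # which Jaccard graphs over diverse compound sets often are; random
    # init keeps refits bit-reproducible across processes.
    model = umap.UMAP(n_neighbors=nn,
                      metric=req.get("metric", "jaccard"),
                      n_components=2,
                      init="random",
                      random_state=int(req.get("seed", 42)))
    emb = model.fit_transform(X)
    return model, emb


def cmd_umap_fit(req):
    import pickle
    model, emb = _fit_umap(req["fps"], req)
    with open(req["model"], "wb") as fh:
        pickle.dump(model, fh)
    _write_coords(req["coords"], emb)
    return {"n": emb.shape[0]}


def cmd_umap_transform(req):
    import pickle
    with open(req["model"], "rb") as fh:
        model = pickle.load(fh)
    X = _read_fps(req["fps"])
    _write_coords(req["coords"], model.transform(X))
    return {"n": X.shape[0]}


def cmd_umap_batch(req):
    """Fit on the reference set and transform any number of query sets in a
    single process (saves the heavy import/JIT cost)."""
    import pickle
    model, emb = _fit_umap(req["fps"], req)
    if req.get("model"):
        with open(req["model"], "wb") as fh:
            pickle.dump(model, fh)
    _write_coords(req["coords"], emb)
    ns = []
    for fps_path, coord_path in zip(req.get("query_fps", []),
                                    req.get("query_coords", [])):
        X = _read_fps(fps_path)
        _write_coords(coord_path, model.transform(X))
        ns.append(X.shape[0])
    return {"n": emb.shape[0], "query_n": ns}


COMMANDS = {
    "canon": cmd_canon,
    "desalt": cmd_desalt,
    "match": cmd_match,
    "descriptors": cmd_descriptors,
    "fingerprints": cmd_fingerprints,
    "transform": cmd_transform,
    "enumerate": cmd_enumerate,
    "sdf_write": cmd_sdf_write,
    "umap_fit": cmd_umap_fit,
    "umap_transform": cmd_umap_transform,
    "umap_batch": cmd_umap_batch,
}


def main(argv):
    cmd, req_path, res_path = argv[1], argv[2], argv[3]
    with open(req_path) as fh:
        req = json.load(fh)
    res = COMMANDS[cmd](req)
    with open(res_path, "w") as fh:
        json.dump(res, fh)


if __name__ == "__main__":
    main(sys.argv)
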