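"""Solve a batch of flux LPs with scipy.optimize.linprog (HiGHS).

Usage: python lp_batch.py <in.json> <out.json>

Input: {"m": int, "n": int, "Ai": [...], "Aj": [...], "Ax": [...],
        "problems": [{"c": [...], "lb": [...], "ub": [...],
                      "maximize": bool}, ...]}
All problems share the equality system A x = 0 (steady state).
Output: [{"status": "optimal|infeasible|unbounded",
          "objective": float|null, "x": [...]|null}, ...]
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import linprog

STATUS = {0: "optimal", 1: "iteration_limit", 2: "infeasible",
          3: "unbounded", 4: "numerical"}


def main(fin, fout):
    with open(fin) as fh:
        job = json.load(fh)
    m, n = job["m"], job["n"]
    A = sparse.coo_matrix(
        (job["Ax"], (job["Ai"], job["Aj"])), shape=(m, n)).tocsr()
    beq = np.zeros(m)
    out = []
    for p in job["problems"]:
        c = np.asarray(p["c"], dtype=float)
        sign = -1.0 if p.get("maximize", True) else 1.0
        bounds = list(zip(p["lb"], p["ub"]))
        res = linprog(sign * c, A_eq=A, b_eq=beq, bounds=bounds,
                      method="highs")
        status = STATUS.get(res.status, "error")
        if status == "optimal":
            out.append({"status": "optimal",
                        "objective": float(sign * res.fun),
                        "x": [float(v) for v in res.x]})
        else:
            out.append({"status": status, "objective": None, "x": None})
    with open(fout, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
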