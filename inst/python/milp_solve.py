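"""Solve a MILP described as JSON with scipy.optimize.milp (HiGHS).

Usage: python milp_solve.py model.json result.json
The model uses 1e30 sentinels for infinite bounds.
"""
import json
import sys

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp
from scipy.sparse import coo_matrix

BIG = 1e29


def main(fin, fout):
    with open(fin) as fh:
        m = json.load(fh)
    n = int(m["n"])
    obj = np.asarray(m["obj"], dtype=float)
    lb = np.asarray(m["lb"], dtype=float)
    ub = np.asarray(m["ub"], dtype=float)
    ub[ub > BIG] = np.inf
    integrality = np.asarray(m["integrality"], dtype=int)
    nrow = int(m["A"]["m"])
    constraints = []
    if nrow:
        A = coo_matrix(
            (np.asarray(m["A"]["val"], dtype=float),
             (np.asarray(m["A"]["row"], dtype=int),
              np.asarray(m["A"]["col"], dtype=int))),
            shape=(nrow, n)).tocsc()
        rlb = np.asarray(m["row_lb"], dtype=float)
        rub = np.asarray(m["row_ub"], dtype=float)
        rlb[rlb < -BIG] = -np.inf
        rub[rub > BIG] = np.inf
        constraints = [LinearConstraint(A, rlb, rub)]
    options = {"mip_rel_gap": float(m.get("mip_gap", 0))}
    tl = float(m.get("time_limit", -1))
    if tl > 0:
        options["time_limit"] = tl
    res = milp(obj, constraints=constraints, integrality=integrality,
               bounds=Bounds(lb, ub), options=options)
    status = {0: "optimal", 1: "limit", 2: "infeasible",
              3: "unbounded"}.get(res.status, "limit")
    out = {"status": status}
    if status == "optimal":
        out["objective"] = float(res.fun)
        out["x"] = [float(v) for v in res.x]
    with open(fout, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
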