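"""Batch 0/1 integer-program solver backing solve_links().

Reads a JSON file with a list of problems (objective vector, sparse
constraint triplets, row bounds), solves each with scipy's HiGHS MILP
interface over binary variables, and writes the solutions as JSON.

Usage: python milp_solve.py input.json output.json
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp


def solve_one(p):
    n = int(p["n"])
    c = np.asarray(p["c"], dtype=float)
    constraints = []
    if int(p["nrow"]) > 0:
        A = sparse.csr_matrix(
            (np.asarray(p["v"], dtype=float),
             (np.asarray(p["i"], dtype=int), np.asarray(p["j"], dtype=int))),
            shape=(int(p["nrow"]), n),
        )
        lb = np.asarray(p["lb"], dtype=float)
        ub = np.asarray(p["ub"], dtype=float)
        constraints = [LinearConstraint(A, lb, ub)]
    vub = np.asarray(p.get("vub", np.ones(n)), dtype=float)
    res = milp(
        c,
        constraints=constraints,
        bounds=Bounds(np.zeros(n), vub),
        integrality=np.ones(n),
    )
    if res.x is None:
        return {"status": int(res.status), "x": [], "obj": None}
    return {
        "status": int(res.status),
        "x": [int(round(v)) for v in res.x],
        "obj": float(res.fun),
    }


def main():
    with open(sys.argv[1]) as fh:
        inp = json.load(fh)
    results = [solve_one(p) for p in inp["problems"]]
    with open(sys.argv[2], "w") as fh:
        json.dump({"results": results}, fh)


if __name__ == "__main__":
    main()
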