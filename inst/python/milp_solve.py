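"""Batch MILP solve helper driven by the R package.

Reads a JSON file with a list of models (linear objective, variable bounds,
integrality flags, sparse constraint triplets with two-sided bounds) and a
shared time limit, solves each with scipy.optimize.milp (HiGHS branch and
bound), and writes a JSON list of results.

Null bounds encode infinities: null in a lower bound means -inf, null in an
upper bound means +inf.
"""
import json
import sys

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp
from scipy.sparse import csr_matrix

STATUS = {
    0: "optimal",
    1: "feasible_time_limited",   # iteration/time limit with incumbent
    2: "infeasible",
}


def arr(x, fill, n=None):
    """JSON scalar/list/None -> 1-d float array with None -> fill."""
    if x is None:
        x = []
    v = np.atleast_1d(np.array(x, dtype=object))
    out = np.array([fill if e is None else float(e) for e in v], dtype=float)
    if n is not None and out.size == 0:
        out = np.full(n, fill)
    return out


def solve_one(model, time_limit):
    nvar = int(model["nvar"])
    c = arr(model["obj"], 0.0)
    integrality = arr(model["integrality"], 0.0)
    lb = arr(model["lb"], -np.inf)
    ub = arr(model["ub"], np.inf)
    rows = arr(model.get("con_i"), 0.0).astype(int)
    cols = arr(model.get("con_j"), 0.0).astype(int)
    vals = arr(model.get("con_v"), 0.0)
    clb = arr(model.get("con_lb"), -np.inf)
    cub = arr(model.get("con_ub"), np.inf)

    constraints = []
    if clb.size:
        ncon = clb.size
        A = csr_matrix((vals, (rows, cols)), shape=(ncon, nvar))
        constraints = [LinearConstraint(A, clb, cub)]

    res = milp(
        c=c,
        constraints=constraints,
        integrality=integrality,
        bounds=Bounds(lb, ub),
        options={"time_limit": float(time_limit), "presolve": True},
    )
    if res.status not in STATUS:
        # HiGHS presolve occasionally reports a solve error on models with
        # fractional constraint targets; retry without presolve
        res = milp(
            c=c,
            constraints=constraints,
            integrality=integrality,
            bounds=Bounds(lb, ub),
            options={"time_limit": float(time_limit), "presolve": False},
        )
    status = STATUS.get(res.status, "error")
    if status == "feasible_time_limited" and res.x is None:
        status = "error"  # limit hit before any incumbent was found
    return {
        "status": status,
        "objective": None if res.x is None else float(res.fun),
        "x": None if res.x is None else [float(v) for v in res.x],
        "message": str(res.message),
    }


def main(argv):
    with open(argv[1]) as fh:
        payload = json.load(fh)
    time_limit = payload.get("time_limit", 10)
    results = [solve_one(m, time_limit) for m in payload["models"]]
    with open(argv[2], "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main(sys.argv)
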