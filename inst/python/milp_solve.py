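"""MILP backend: solve a sparse-triplet model with HiGHS via scipy.optimize.milp.

Usage: python milp_solve.py model.json solution.json
Bounds with absolute value >= 1e29 are treated as infinite.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

INF_SENTINEL = 1e29


def _definitize(a, sign):
    a = np.asarray(a, dtype=float)
    a[a >= INF_SENTINEL] = np.inf
    a[a <= -INF_SENTINEL] = -np.inf
    return a


def main(inp, outp):
    with open(inp) as fh:
        m = json.load(fh)
    n = int(m["nvar"])
    c = np.asarray(m["obj"], dtype=float)
    integrality = np.asarray(m["integrality"], dtype=int)
    bounds = Bounds(_definitize(m["lb"], -1), _definitize(m["ub"], 1))
    constraints = []
    if int(m.get("nrow", 0)) > 0:
        a = sparse.csc_matrix(
            (np.asarray(m["ax"], dtype=float),
             (np.asarray(m["ai"], dtype=int), np.asarray(m["aj"], dtype=int))),
            shape=(int(m["nrow"]), n),
        )
        constraints = [LinearConstraint(a, _definitize(m["row_lb"], -1),
                                        _definitize(m["row_ub"], 1))]
    options = {}
    if m.get("time_limit") is not None:
        options["time_limit"] = float(m["time_limit"])
    res = milp(c=c, constraints=constraints, integrality=integrality,
               bounds=bounds, options=options)
    dual = getattr(res, "mip_dual_bound", None)
    out = {
        "status": int(res.status),
        "message": str(res.message),
        "objective": None if res.fun is None else float(res.fun),
        "mip_dual_bound": None if dual is None else float(dual),
        "x": None if res.x is None else [float(v) for v in res.x],
    }
    with open(outp, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
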