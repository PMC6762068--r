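#!/usr/bin/env python
"""Independent QP oracle for the one-class SVM dual.

Solves  min 1/2 a' K a   s.t.  sum(a) = 1,  0 <= a <= C
with a generic constrained optimizer (scipy trust-constr, exact Jacobian and
Hessian). Used by the R test suite as a reference implementation; it shares
no code with the package's SMO solver.

Usage: python qp_oracle.py problems.json results.json
Input: [{"K": [[...]], "C": c}, ...]
Output: [{"alpha": [...], "objective": obj}, ...]
"""
import json
import sys

import numpy as np
from scipy.optimize import LinearConstraint, minimize


def solve(K, C):
    K = np.asarray(K, dtype=float)
    n = K.shape[0]
    x0 = np.full(n, 1.0 / n)
    res = minimize(
        lambda a: 0.5 * a @ K @ a,
        x0,
        jac=lambda a: K @ a,
        hess=lambda a: K,
        bounds=[(0.0, C)] * n,
        constraints=[LinearConstraint(np.ones(n), 1.0, 1.0)],
        method="trust-constr",
        options={"gtol": 1e-12, "xtol": 1e-14, "maxiter": 5000},
    )
    a = np.clip(res.x, 0.0, C)
    a *= 1.0 / a.sum()
    return a, float(0.5 * a @ K @ a)


def main():
    with open(sys.argv[1]) as fh:
        problems = json.load(fh)
    out = []
    for p in problems:
        alpha, obj = solve(p["K"], p["C"])
        out.append({"alpha": alpha.tolist(), "objective": obj})
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
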