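#!/usr/bin/env python
"""Reference gaussian mean-shift, used only as an independent test oracle.

Naive direct translation of the update rule: each point is shifted to the
exp(-||.||^2 / (2 h^2))-weighted mean of the data until the displacement is
below epsilon; converged modes closer than the merge radius share a label
(single linkage via connected components).

Usage: mean_shift_reference.py points.csv h epsilon max_iter merge_radius
Prints one 1-based cluster label per point, first-occurrence ordered.
"""
import sys

import numpy as np


def shift(x, data, h, eps, max_iter):
    for _ in range(max_iter):
        w = np.exp(-((data - x) ** 2).sum(axis=1) / (2.0 * h * h))
        s = w.sum()
        if s == 0.0:
            return x
        new = (data * w[:, None]).sum(axis=0) / s
        if np.linalg.norm(new - x) < eps:
            return new
        x = new
    return x


def main():
    path, h, eps, max_iter, radius = (
        sys.argv[1],
        float(sys.argv[2]),
        float(sys.argv[3]),
        int(sys.argv[4]),
        float(sys.argv[5]),
    )
    data = np.loadtxt(path, delimiter=",", ndmin=2)
    modes = np.vstack([shift(p.copy(), data, h, eps, max_iter) for p in data])
    n = len(modes)
    # connected components of the < radius graph
    adj = np.linalg.norm(modes[:, None, :] - modes[None, :, :], axis=2) < radius
    labels = np.zeros(n, dtype=int)
    nxt = 0
    for i in range(n):
        if labels[i]:
            continue
        nxt += 1
        stack = [i]
        labels[i] = nxt
        while stack:
            j = stack.pop()
            for k in np.where(adj[j] & (labels == 0))[0]:
                labels[k] = nxt
                stack.append(k)
    print("\n".join(str(l) for l in labels))


if __name__ == "__main__":
    main()
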