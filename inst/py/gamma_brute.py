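"""Independent brute-force 3D gamma passing rate.

Reads a JSON case description {dim, spacing_mm, ref, ev, dd_pct, dta_mm,
ldt_pct} (volumes flattened in column-major order) and prints the gamma
passing rate computed by exhaustive lattice search (step dta/10 out to dta,
which fully determines pass/fail) with its own trilinear interpolation.
Written as an independent cross-check for the R implementation; shares no
code with it.
"""
import json
import sys

import numpy as np


def trilinear(vol, x, y, z):
    """Vectorized trilinear sample at fractional voxel coords; NaN outside."""
    nx, ny, nz = vol.shape
    ok = (x >= 0) & (x <= nx - 1) & (y >= 0) & (y <= ny - 1) & \
         (z >= 0) & (z <= nz - 1)
    xc = np.clip(x, 0, nx - 1.0001)
    yc = np.clip(y, 0, ny - 1.0001)
    zc = np.clip(z, 0, nz - 1.0001)
    x0 = np.floor(xc).astype(int)
    y0 = np.floor(yc).astype(int)
    z0 = np.floor(zc).astype(int)
    fx, fy, fz = xc - x0, yc - y0, zc - z0
    out = np.zeros_like(x, dtype=float)
    for dx in (0, 1):
        for dy in (0, 1):
            for dz in (0, 1):
                w = (fx if dx else 1 - fx) * (fy if dy else 1 - fy) * \
                    (fz if dz else 1 - fz)
                out += w * vol[x0 + dx, y0 + dy, z0 + dz]
    out[~ok] = np.nan
    return out


def main(path):
    with open(path) as fh:
        case = json.load(fh)
    dim = tuple(case["dim"])
    sp = case["spacing_mm"]
    ref = np.asarray(case["ref"], dtype=float).reshape(dim, order="F")
    ev = np.asarray(case["ev"], dtype=float).reshape(dim, order="F")
    dd = case["dd_pct"] / 100.0 * ref.max()
    dta = case["dta_mm"]
    ldt = case["ldt_pct"] / 100.0 * ref.max()

    ii, jj, kk = np.where(ref >= ldt)
    rv = ref[ii, jj, kk]
    step = dta / 10.0
    k = int(np.floor(dta / step + 1e-9))
    offs = np.array([(a, b, c) for a in range(-k, k + 1)
                     for b in range(-k, k + 1)
                     for c in range(-k, k + 1)], dtype=float) * step
    offs = offs[np.sqrt((offs ** 2).sum(1)) <= dta + 1e-9]

    passed = np.zeros(len(rv), dtype=bool)
    for off in offs:
        active = ~passed
        if not active.any():
            break
        evs = trilinear(ev, ii[active] + off[0] / sp,
                        jj[active] + off[1] / sp, kk[active] + off[2] / sp)
        g2 = ((evs - rv[active]) / dd) ** 2 + (off ** 2).sum() / dta ** 2
        hit = np.where(active)[0][np.nan_to_num(g2, nan=np.inf) <= 1 + 1e-9]
        passed[hit] = True
    print("%.10f" % (100.0 * passed.mean()))


if __name__ == "__main__":
    main(sys.argv[1])
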