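#!/usr/bin/env python
"""Independent oracle for the intensity/texture radiomics feature bank.

Reads a CSV of in-mask voxels (columns i,j,k,value,level; 1-based indices)
plus grid metadata from the command line, recomputes the 93 intensity and
texture features (18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM,
14 GLDM) from their standard definitions using numpy/scipy building blocks,
and writes name,value pairs as CSV.  Shares no code with the R package; it
exists so the R implementation can be cross-checked in tests.

Usage:
  python radiomics_oracle.py IN.csv OUT.csv NI NJ NK NLEVELS SX SY SZ
"""
import sys

import numpy as np
from scipy import ndimage, stats

OFFS26 = [(di, dj, dk)
          for di in (-1, 0, 1) for dj in (-1, 0, 1) for dk in (-1, 0, 1)
          if (di, dj, dk) != (0, 0, 0)]
# one representative of each antipodal pair
OFFS13 = [o for o in OFFS26
          if (o[2] > 0) or (o[2] == 0 and o[1] > 0)
          or (o[2] == 0 and o[1] == 0 and o[0] > 0)]


def shifted(a, off, fill=np.nan):
    out = np.full_like(a, fill)
    src = [slice(None)] * 3
    dst = [slice(None)] * 3
    for ax, o in enumerate(off):
        n = a.shape[ax]
        if o >= 0:
            dst[ax] = slice(0, n - o)
            src[ax] = slice(o, n)
        else:
            dst[ax] = slice(-o, n)
            src[ax] = slice(0, n + o)
    out[tuple(dst)] = a[tuple(src)]
    return out


def first_order(vals, spacing, nbins):
    x = vals
    n = x.size
    mu = x.mean()
    m2 = ((x - mu) ** 2).mean()
    q10, q25, q50, q75, q90 = np.percentile(x, [10, 25, 50, 75, 90])
    rob = x[(x >= q10) & (x <= q90)]
    rng = x.max() - x.min()
    if rng == 0:
        p = np.array([1.0])
    else:
        w = rng / nbins
        lev = np.minimum(np.floor((x - x.min()) / w).astype(int) + 1, nbins)
        p = np.bincount(lev, minlength=nbins + 1)[1:] / n
        p = p[p > 0]
    return {
        "firstorder_Energy": float((x ** 2).sum()),
        "firstorder_TotalEnergy": float(np.prod(spacing) * (x ** 2).sum()),
        "firstorder_Entropy": float(-(p * np.log2(p)).sum()),
        "firstorder_Minimum": float(x.min()),
        "firstorder_Percentile10": float(q10),
        "firstorder_Percentile90": float(q90),
        "firstorder_Maximum": float(x.max()),
        "firstorder_Mean": float(mu),
        "firstorder_Median": float(q50),
        "firstorder_InterquartileRange": float(q75 - q25),
        "firstorder_Range": float(rng),
        "firstorder_MeanAbsoluteDeviation": float(np.abs(x - mu).mean()),
        "firstorder_RobustMeanAbsoluteDeviation":
            float(np.abs(rob - rob.mean()).mean()),
        "firstorder_RootMeanSquared": float(np.sqrt((x ** 2).mean())),
        "firstorder_Skewness": float(stats.skew(x, bias=True))
            if m2 > 0 else 0.0,
        "firstorder_Kurtosis": float(stats.kurtosis(x, fisher=False,
                                                    bias=True))
            if m2 > 0 else 0.0,
        "firstorder_Variance": float(m2),
        "firstorder_Uniformity": float((p ** 2).sum()),
    }


def glcm_one(p):
    ng = p.shape[0]
    i = np.arange(1, ng + 1)[:, None] * np.ones((1, ng))
    j = i.T
    px = p.sum(axis=1)
    mu = (i * p).sum()
    sigma2 = (((i - mu) ** 2) * p).sum()
    kd = np.arange(0, ng)
    p_diff = np.array([p[np.abs(i - j) == k].sum() for k in kd])
    ks = np.arange(2, 2 * ng + 1)
    p_sum = np.array([p[(i + j) == k].sum() for k in ks])

    def ent(q):
        q = q[q > 0]
        return float(-(q * np.log2(q)).sum())

    hx = ent(px)
    hxy = ent(p)
    pxy = np.outer(px, px)
    mask = p > 0
    hxy1 = float(-(p[mask] * np.log2(pxy[mask])).sum())
    m2q = pxy > 0
    hxy2 = float(-(pxy[m2q] * np.log2(pxy[m2q])).sum())
    da = float((kd * p_diff).sum())
    act = px > 0
    mcc = 1.0
    if act.sum() >= 2:
        ps = p[np.ix_(act, act)]
        pxa = px[act]
        q = np.zeros_like(ps)
        for k in range(ps.shape[0]):
            q += np.outer(ps[:, k], ps[:, k]) / (pxa[:, None] * pxa[k])
        ev = np.sort(np.real(np.linalg.eigvals(q)))[::-1]
        mcc = float(np.sqrt(max(ev[1], 0)))
    off = i != j
    return {
        "glcm_Autocorrelation": float((i * j * p).sum()),
        "glcm_JointAverage": float(mu),
        "glcm_ClusterProminence": float((((i + j - 2 * mu) ** 4) * p).sum()),
        "glcm_ClusterShade": float((((i + j - 2 * mu) ** 3) * p).sum()),
        "glcm_ClusterTendency": float((((i + j - 2 * mu) ** 2) * p).sum()),
        "glcm_Contrast": float((((i - j) ** 2) * p).sum()),
        "glcm_Correlation":
            float(((i * j * p).sum() - mu ** 2) / sigma2) if sigma2 > 0
            else 1.0,
        "glcm_DifferenceAverage": da,
        "glcm_DifferenceEntropy": ent(p_diff),
        "glcm_DifferenceVariance": float((((kd - da) ** 2) * p_diff).sum()),
        "glcm_JointEnergy": float((p ** 2).sum()),
        "glcm_JointEntropy": hxy,
        "glcm_Imc1": (hxy - hxy1) / hx if hx > 0 else 0.0,
        "glcm_Imc2": float(np.sqrt(max(1 - np.exp(-2 * (hxy2 - hxy)), 0))),
        "glcm_Idm": float((p / (1 + (i - j) ** 2)).sum()),
        "glcm_Idmn": float((p / (1 + ((i - j) / ng) ** 2)).sum()),
        "glcm_Id": float((p / (1 + np.abs(i - j))).sum()),
        "glcm_Idn": float((p / (1 + np.abs(i - j) / ng)).sum()),
        "glcm_InverseVariance":
            float((p[off] / ((i - j)[off] ** 2)).sum()),
        "glcm_MaximumProbability": float(p.max()),
        "glcm_MCC": mcc,
        "glcm_SumAverage": float((ks * p_sum).sum()),
        "glcm_SumEntropy": ent(p_sum),
        "glcm_SumSquares": float(sigma2),
    }


def glcm(lev, ng):
    per_dir = []
    for off in OFFS13:
        sh = shifted(lev, off)
        ok = ~np.isnan(lev) & ~np.isnan(sh)
        if not ok.any():
            continue
        a = lev[ok].astype(int)
        b = sh[ok].astype(int)
        cnt = np.zeros((ng, ng))
        np.add.at(cnt, (a - 1, b - 1), 1)
        p = cnt + cnt.T
        per_dir.append(glcm_one(p / p.sum()))
    keys = per_dir[0].keys()
    return {k: float(np.mean([d[k] for d in per_dir])) for k in keys}


def rl_features(P, np_vox, prefix, names):
    nr = P.sum()
    g = np.arange(1, P.shape[0] + 1)[:, None] * np.ones((1, P.shape[1]))
    l = np.arange(1, P.shape[1] + 1)[None, :] * np.ones((P.shape[0], 1))
    p = P / nr
    mug = (g * p).sum()
    mul = (l * p).sum()
    pp = p[p > 0]
    vals = [
        (P / l ** 2).sum() / nr, (P * l ** 2).sum() / nr,
        (P.sum(axis=1) ** 2).sum() / nr, (P.sum(axis=1) ** 2).sum() / nr ** 2,
        (P.sum(axis=0) ** 2).sum() / nr, (P.sum(axis=0) ** 2).sum() / nr ** 2,
        nr / np_vox,
        (((g - mug) ** 2) * p).sum(), (((l - mul) ** 2) * p).sum(),
        -(pp * np.log2(pp)).sum(),
        (P / g ** 2).sum() / nr, (P * g ** 2).sum() / nr,
        (P / (g ** 2 * l ** 2)).sum() / nr, (P * g ** 2 / l ** 2).sum() / nr,
        (P * l ** 2 / g ** 2).sum() / nr, (P * g ** 2 * l ** 2).sum() / nr,
    ]
    return {prefix + "_" + n: float(v) for n, v in zip(names, vals)}


RL_NAMES = ["ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
            "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
            "RunLengthNonUniformityNormalized", "RunPercentage",
            "GrayLevelVariance", "RunVariance", "RunEntropy",
            "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
            "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
            "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"]
SZ_NAMES = ["SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
            "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
            "SizeZoneNonUniformityNormalized", "ZonePercentage",
            "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
            "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
            "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
            "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"]


def glrlm(lev, ng, np_vox):
    dims = lev.shape
    per_dir = []
    for off in OFFS13:
        runs = {}
        # start points: positions whose predecessor lies outside the grid
        for idx in np.ndindex(dims):
            prev = tuple(idx[a] - off[a] for a in range(3))
            if all(0 <= prev[a] < dims[a] for a in range(3)):
                continue
            cur = idx
            run_level, run_len = None, 0
            while all(0 <= cur[a] < dims[a] for a in range(3)):
                v = lev[cur]
                if np.isnan(v):
                    if run_level is not None:
                        runs[(int(run_level), run_len)] = \
                            runs.get((int(run_level), run_len), 0) + 1
                    run_level, run_len = None, 0
                elif v == run_level:
                    run_len += 1
                else:
                    if run_level is not None:
                        runs[(int(run_level), run_len)] = \
                            runs.get((int(run_level), run_len), 0) + 1
                    run_level, run_len = v, 1
                cur = tuple(cur[a] + off[a] for a in range(3))
            if run_level is not None:
                runs[(int(run_level), run_len)] = \
                    runs.get((int(run_level), run_len), 0) + 1
        maxlen = max(k[1] for k in runs)
        P = np.zeros((ng, maxlen))
        for (gl, rl), c in runs.items():
            P[gl - 1, rl - 1] += c
        per_dir.append(rl_features(P, np_vox, "glrlm", RL_NAMES))
    keys = per_dir[0].keys()
    return {k: float(np.mean([d[k] for d in per_dir])) for k in keys}


def glszm(lev, ng, np_vox):
    zones = []
    struct = np.ones((3, 3, 3))
    for g in range(1, ng + 1):
        lab, nlab = ndimage.label(np.nan_to_num(lev, nan=-1) == g,
                                  structure=struct)
        for z in range(1, nlab + 1):
            zones.append((g, int((lab == z).sum())))
    maxs = max(z[1] for z in zones)
    P = np.zeros((ng, maxs))
    for g, s in zones:
        P[g - 1, s - 1] += 1
    return rl_features(P, np_vox, "glszm", SZ_NAMES)


def ngtdm(lev, ng):
    s_sum = np.zeros_like(lev)
    s_cnt = np.zeros_like(lev)
    for off in OFFS26:
        sh = shifted(lev, off)
        ok = ~np.isnan(sh)
        s_sum = np.where(ok, s_sum + np.nan_to_num(sh), s_sum)
        s_cnt = np.where(ok, s_cnt + 1, s_cnt)
    valid = ~np.isnan(lev) & (s_cnt > 0)
    g = lev[valid].astype(int)
    abar = s_sum[valid] / s_cnt[valid]
    nvp = valid.sum()
    n_i = np.bincount(g, minlength=ng + 1)[1:].astype(float)
    s_i = np.array([np.abs(i - abar[g == i]).sum()
                    for i in range(1, ng + 1)])
    p_i = n_i / nvp
    act = np.where(p_i > 0)[0] + 1
    ngp = len(act)
    den = (p_i * s_i).sum()
    coarse = 1 / den if den > 0 else 1e6
    if ngp > 1:
        con = (np.add.outer(act * 0.0, act * 0.0) +
               np.subtract.outer(act, act) ** 2 *
               np.outer(p_i[act - 1], p_i[act - 1])).sum() \
            / (ngp * (ngp - 1)) * s_i.sum() / nvp
    else:
        con = 0.0
    pa = p_i[act - 1]
    sa = s_i[act - 1]
    bden = np.abs(np.subtract.outer(act * pa, act * pa)).sum()
    busy = (p_i * s_i).sum() / bden if bden > 0 else 0.0
    comp = (np.abs(np.subtract.outer(act, act)) *
            np.add.outer(pa * sa, pa * sa) /
            np.add.outer(pa, pa)).sum() / nvp
    stre = (np.add.outer(pa, pa) * np.subtract.outer(act, act) ** 2).sum() \
        / s_i.sum() if s_i.sum() > 0 else 0.0
    return {"ngtdm_Coarseness": float(coarse), "ngtdm_Contrast": float(con),
            "ngtdm_Busyness": float(busy), "ngtdm_Complexity": float(comp),
            "ngtdm_Strength": float(stre)}


def gldm(lev, ng):
    dep = np.zeros_like(lev)
    for off in OFFS26:
        sh = shifted(lev, off)
        dep = dep + np.where(~np.isnan(lev) & ~np.isnan(sh) & (lev == sh),
                             1, 0)
    valid = ~np.isnan(lev)
    g = lev[valid].astype(int)
    j = dep[valid].astype(int) + 1
    P = np.zeros((ng, int(j.max())))
    np.add.at(P, (g - 1, j - 1), 1)
    nz = P.sum()
    gg = np.arange(1, ng + 1)[:, None] * np.ones((1, P.shape[1]))
    jj = np.arange(1, P.shape[1] + 1)[None, :] * np.ones((ng, 1))
    p = P / nz
    mug = (gg * p).sum()
    muj = (jj * p).sum()
    pp = p[p > 0]
    return {
        "gldm_SmallDependenceEmphasis": float((P / jj ** 2).sum() / nz),
        "gldm_LargeDependenceEmphasis": float((P * jj ** 2).sum() / nz),
        "gldm_GrayLevelNonUniformity":
            float((P.sum(axis=1) ** 2).sum() / nz),
        "gldm_DependenceNonUniformity":
            float((P.sum(axis=0) ** 2).sum() / nz),
        "gldm_DependenceNonUniformityNormalized":
            float((P.sum(axis=0) ** 2).sum() / nz ** 2),
        "gldm_GrayLevelVariance": float((((gg - mug) ** 2) * p).sum()),
        "gldm_DependenceVariance": float((((jj - muj) ** 2) * p).sum()),
        "gldm_DependenceEntropy": float(-(pp * np.log2(pp)).sum()),
        "gldm_LowGrayLevelEmphasis": float((P / gg ** 2).sum() / nz),
        "gldm_HighGrayLevelEmphasis": float((P * gg ** 2).sum() / nz),
        "gldm_SmallDependenceLowGrayLevelEmphasis":
            float((P / (gg ** 2 * jj ** 2)).sum() / nz),
        "gldm_SmallDependenceHighGrayLevelEmphasis":
            float((P * gg ** 2 / jj ** 2).sum() / nz),
        "gldm_LargeDependenceLowGrayLevelEmphasis":
            float((P * jj ** 2 / gg ** 2).sum() / nz),
        "gldm_LargeDependenceHighGrayLevelEmphasis":
            float((P * gg ** 2 * jj ** 2).sum() / nz),
    }


def main():
    inp, outp = sys.argv[1], sys.argv[2]
    ni, nj, nk, nlev = (int(v) for v in sys.argv[3:7])
    spacing = [float(v) for v in sys.argv[7:10]]
    data = np.loadtxt(inp, delimiter=",", skiprows=1, ndmin=2)
    lev = np.full((ni, nj, nk), np.nan)
    val = np.full((ni, nj, nk), np.nan)
    ii = data[:, 0].astype(int) - 1
    jj = data[:, 1].astype(int) - 1
    kk = data[:, 2].astype(int) - 1
    val[ii, jj, kk] = data[:, 3]
    lev[ii, jj, kk] = data[:, 4]
    np_vox = len(ii)
    feats = {}
    feats.update(first_order(data[:, 3], spacing, nlev))
    feats.update(glcm(lev, nlev))
    feats.update(glrlm(lev, nlev, np_vox))
    feats.update(glszm(lev, nlev, np_vox))
    feats.update(ngtdm(lev, nlev))
    feats.update(gldm(lev, nlev))
    with open(outp, "w") as fh:
        fh.write("name,value\n")
        for k, v in feats.items():
            fh.write("%s,%.17g\n" % (k, v))


if __name__ == "__main__":
    main()
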