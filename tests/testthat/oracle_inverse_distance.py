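"""Arbitrary-precision oracle for the inverse-distance ancestry formulas.

Reads a TSV of queries, one per line:
    eq3 <dim> <point...> <centroidA...> <centroidB...>
    eq4 <dim> <point...> <c1...> <c2...> <c3...>
and writes, per line, tab-separated ancestry proportions (2 values for
eq3, 3 for eq4) evaluated with mpmath at 40 significant digits.

eq3: drop the point perpendicularly onto the segment's line; with L1,
L2 the distances from the foot to the two endpoints, the first
endpoint's share is (1/L1) / (1/L1 + 1/L2).

eq4: for each triangle side, the perpendicular distance H and the
foot-to-endpoint distances L define a two-way share; population shares
are the 1/H-weighted side shares normalized by sum(1/H).
"""
import sys
from mpmath import mp, mpf, sqrt

mp.dps = 40


def vec(tokens):
    return [mpf(t) for t in tokens]


def sub(a, b):
    return [x - y for x, y in zip(a, b)]


def dot(a, b):
    return sum(x * y for x, y in zip(a, b))


def dist(a, b):
    return sqrt(dot(sub(a, b), sub(a, b)))


def foot_on_line(p, a, b):
    u = sub(b, a)
    t = dot(sub(p, a), u) / dot(u, u)
    return [x + t * y for x, y in zip(a, u)]


def eq3(p, a, b):
    f = foot_on_line(p, a, b)
    L1, L2 = dist(f, a), dist(f, b)
    share = (1 / L1) / (1 / L1 + 1 / L2)
    return [share, 1 - share]


def eq4(p, c1, c2, c3):
    tri = [c1, c2, c3]
    sides = [(0, 1), (0, 2), (1, 2)]
    inv_h = []
    side_share = []
    for i, j in sides:
        f = foot_on_line(p, tri[i], tri[j])
        h = dist(p, f)
        inv_h.append(1 / h)
        L1, L2 = dist(f, tri[i]), dist(f, tri[j])
        s = (1 / L1) / (1 / L1 + 1 / L2)
        side_share.append((s, 1 - s))
    total = sum(inv_h)
    props = [mpf(0)] * 3
    for k, (i, j) in enumerate(sides):
        props[i] += inv_h[k] * side_share[k][0]
        props[j] += inv_h[k] * side_share[k][1]
    return [x / total for x in props]


def main(inp, outp):
    with open(inp) as fin, open(outp, "w") as fout:
        for line in fin:
            tok = line.split()
            mode, d = tok[0], int(tok[1])
            nums = vec(tok[2:])
            p = nums[:d]
            cents = [nums[d * (i + 1):d * (i + 2)]
                     for i in range(len(nums) // d - 1)]
            if mode == "eq3":
                res = eq3(p, *cents)
            elif mode == "eq4":
                res = eq4(p, *cents)
            else:
                raise ValueError("unknown mode " + mode)
            fout.write("\t".join(mp.nstr(x, 25) for x in res) + "\n")


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
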