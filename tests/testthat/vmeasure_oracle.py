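"""Reference V-measure values via scikit-learn for a batch of label pairs.

Reads a CSV with columns pair,C,K; writes a CSV with pair,h,c,v.
"""
import csv
import sys

from sklearn.metrics import homogeneity_completeness_v_measure

pairs = {}
with open(sys.argv[1], newline="") as fh:
    for row in csv.DictReader(fh):
        pairs.setdefault(row["pair"], ([], []))
        pairs[row["pair"]][0].append(row["C"])
        pairs[row["pair"]][1].append(row["K"])

with open(sys.argv[2], "w", newline="") as fh:
    out = csv.writer(fh)
    out.writerow(["pair", "h", "c", "v"])
    for pair, (C, K) in pairs.items():
        h, c, v = homogeneity_completeness_v_measure(C, K)
        out.writerow([pair, repr(h), repr(c), repr(v)])
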