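"""Array-transfer helpers for the psolstm R package.

Converts between the DEAP/SEED on-disk dialects (Python pickle, MATLAB v5)
and a trivial exchange layout the R side reads directly: one little-endian
C-order float64 .bin per array plus a meta.json with shapes.

Usage:
  python eeg_io.py read_deap  <file> <outdir>
  python eeg_io.py write_deap <indir> <file>
  python eeg_io.py read_seed  <file> <outdir>
"""
import json
import os
import pickle
import re
import sys

import numpy as np


def _fail(msg, code=2):
    sys.stderr.write("eeg_io error: %s\n" % msg)
    sys.exit(code)


def _dump(arr, path):
    np.ascontiguousarray(arr, dtype="<f8").tofile(path)


def _load_container(path):
    """DEAP per-subject container: pickle by default, MATLAB if .mat."""
    if path.endswith(".mat"):
        from scipy.io import loadmat
        raw = loadmat(path)
        return {k: v for k, v in raw.items() if not k.startswith("__")}
    with open(path, "rb") as fh:
        return pickle.load(fh, encoding="latin1")


def read_deap(path, outdir):
    d = _load_container(path)
    for key in ("data", "labels"):
        if key not in d:
            _fail("missing key '%s' in %s" % (key, path))
    data = np.asarray(d["data"], dtype=np.float64)
    labels = np.asarray(d["labels"], dtype=np.float64)
    _dump(data, os.path.join(outdir, "data.bin"))
    _dump(labels, os.path.join(outdir, "labels.bin"))
    with open(os.path.join(outdir, "meta.json"), "w") as fh:
        json.dump({"data_shape": list(data.shape),
                   "labels_shape": list(labels.shape)}, fh)


def write_deap(indir, path):
    with open(os.path.join(indir, "meta.json")) as fh:
        meta = json.load(fh)
    data = np.fromfile(os.path.join(indir, "data.bin"),
                       dtype="<f8").reshape(meta["data_shape"])
    labels = np.fromfile(os.path.join(indir, "labels.bin"),
                         dtype="<f8").reshape(meta["labels_shape"])
    with open(path, "wb") as fh:
        pickle.dump({"data": data, "labels": labels}, fh, protocol=2)


def read_seed(path, outdir):
    """SEED session file: variables named like 'djc_eeg1' .. 'djc_eeg15',
    each channels x samples. Emitted in trial-number order."""
    from scipy.io import loadmat
    raw = loadmat(path)
    pat = re.compile(r"_eeg(\d+)$")
    trials = []
    for k, v in raw.items():
        if k.startswith("__"):
            continue
        m = pat.search(k)
        if m and isinstance(v, np.ndarray) and v.ndim == 2:
            trials.append((int(m.group(1)), k, np.asarray(v, dtype=np.float64)))
    if not trials:
        _fail("no '*_eeg<k>' trial matrices found in %s" % path)
    trials.sort(key=lambda t: t[0])
    meta = []
    for idx, (num, name, arr) in enumerate(trials):
        fname = "trial_%03d.bin" % idx
        _dump(arr, os.path.join(outdir, fname))
        meta.append({"index": num, "name": name, "file": fname,
                     "shape": list(arr.shape)})
    with open(os.path.join(outdir, "meta.json"), "w") as fh:
        json.dump({"trials": meta}, fh)


def main(argv):
    if len(argv) != 4:
        _fail("usage: eeg_io.py {read_deap|write_deap|read_seed} <in> <out>", 1)
    cmd, a, b = argv[1], argv[2], argv[3]
    if cmd == "read_deap":
        read_deap(a, b)
    elif cmd == "write_deap":
        write_deap(a, b)
    elif cmd == "read_seed":
        read_seed(a, b)
    else:
        _fail("unknown command '%s'" % cmd, 1)


if __name__ == "__main__":
    main(sys.argv)
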