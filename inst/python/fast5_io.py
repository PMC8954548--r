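"""fast5 (HDF5) read/write helper.

Called by the R package as a subprocess.  Metadata crosses the process
boundary as JSON; signal values as raw little-endian float64 so round trips
are bit-exact.  Supports the single-read layout (Raw/Reads/Read_<i>/Signal)
and the multi-read layout (read_<id>/Raw/Signal).  On read, signals are
converted to pA when calibration attributes (digitisation, offset, range)
are present.
"""
import json
import struct
import sys


def fail(msg):
    print(json.dumps({"error": str(msg)}))
    sys.exit(0)


def read_f64(path, counts):
    out = []
    with open(path, "rb") as fh:
        for n in counts:
            out.append(struct.unpack("<%dd" % n, fh.read(8 * n)))
    return out


def main():
    try:
        import h5py
    except ImportError:
        fail("h5py not available")

    if len(sys.argv) < 3:
        fail("usage: fast5_io.py write <spec.json> | read <path> <out.f64>")
    cmd, path = sys.argv[1], sys.argv[2]

    if cmd == "write":
        with open(path) as fh:
            spec = json.load(fh)
        counts = [rec["n"] for rec in spec["reads"]]
        signals = read_f64(spec["signal_file"], counts)
        with h5py.File(spec["path"], "w") as f:
            for i, rec in enumerate(spec["reads"]):
                if spec["layout"] == "single":
                    g = f.create_group("Raw/Reads/Read_%d" % i)
                    g.attrs["read_id"] = rec["read_id"]
                    g.create_dataset("Signal", data=signals[i],
                                     dtype="float64")
                else:
                    g = f.create_group("read_%s/Raw" % rec["read_id"])
                    g.create_dataset("Signal", data=signals[i],
                                     dtype="float64")
        print(json.dumps({"ok": True}))
        return

    if cmd != "read":
        fail("unknown command " + cmd)
    if len(sys.argv) < 4:
        fail("read needs an output signal path")
    out_bin = sys.argv[3]
    if not h5py.is_hdf5(path):
        fail("%s is not an HDF5 file" % path)
    reads = []
    with h5py.File(path, "r") as f:
        if "Raw" in f and "Reads" in f["Raw"]:
            for name, grp in f["Raw/Reads"].items():
                if "Signal" not in grp:
                    fail("missing signal dataset at Raw/Reads/%s/Signal"
                         % name)
                rid = grp.attrs.get("read_id", name)
                if isinstance(rid, bytes):
                    rid = rid.decode()
                reads.append((str(rid), grp, grp["Signal"][()]))
        else:
            for name in f:
                if not name.startswith("read_"):
                    continue
                grp = f[name]
                if "Raw" not in grp or "Signal" not in grp["Raw"]:
                    fail("missing signal dataset at %s/Raw/Signal" % name)
                reads.append((name[len("read_"):], grp,
                              grp["Raw/Signal"][()]))
            if not reads:
                fail("no reads found (tried Raw/Reads/*/Signal and "
                     "read_*/Raw/Signal)")
        meta = []
        with open(out_bin, "wb") as ob:
            for rid, grp, sig in reads:
                cal = None
                for cand in ("channel_id", "UniqueGlobalKey/channel_id"):
                    node = grp.get(cand)
                    if node is None and cand in f:
                        node = f[cand]
                    if node is not None and "digitisation" in node.attrs:
                        cal = node.attrs
                        break
                vals = sig.astype("float64")
                if cal is not None:
                    vals = (vals + float(cal["offset"])) * \
                        float(cal["range"]) / float(cal["digitisation"])
                ob.write(struct.pack("<%dd" % len(vals), *vals.tolist()))
                meta.append({"read_id": rid, "n": int(len(vals))})
    print(json.dumps({"reads": meta}))


if __name__ == "__main__":
    main()
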