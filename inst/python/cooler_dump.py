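"""Dump a single-resolution cooler HDF5 container to TSV tables.

Usage: python cooler_dump.py <file.cool> <outdir>

Writes chroms.tsv, bins.tsv, pixels.tsv and binsize.txt into <outdir>.
Multi-resolution containers are rejected with a message listing the
resolution paths they hold.
"""
import sys

import h5py


def main(path, outdir):
    import os

    with h5py.File(path, "r") as f:
        if "resolutions" in f:
            res = sorted(f["resolutions"].keys(), key=lambda r: int(r))
            sys.stderr.write(
                "multi-resolution container; open one of: "
                + ", ".join("/resolutions/" + r for r in res)
                + "\n"
            )
            sys.exit(2)
        for grp in ("chroms", "bins", "pixels"):
            if grp not in f:
                sys.stderr.write("not a cooler file: missing group %r\n" % grp)
                sys.exit(2)
        names = [n.decode() if isinstance(n, bytes) else str(n) for n in f["chroms/name"][:]]
        lengths = f["chroms/length"][:]
        with open(os.path.join(outdir, "chroms.tsv"), "w") as out:
            out.write("name\tlength\n")
            for n, l in zip(names, lengths):
                out.write("%s\t%d\n" % (n, l))
        chrom_idx = f["bins/chrom"][:]
        starts = f["bins/start"][:]
        ends = f["bins/end"][:]
        weights = f["bins/weight"][:] if "weight" in f["bins"] else None
        with open(os.path.join(outdir, "bins.tsv"), "w") as out:
            cols = "bin_id\tchrom\tstart\tend"
            if weights is not None:
                cols += "\tweight"
            out.write(cols + "\n")
            for i in range(len(starts)):
                row = "%d\t%s\t%d\t%d" % (i, names[chrom_idx[i]], starts[i], ends[i])
                if weights is not None:
                    row += "\t%r" % float(weights[i])
                out.write(row + "\n")
        binsize = f.attrs.get("bin-size")
        if binsize is None:
            binsize = int(ends[0] - starts[0])
        with open(os.path.join(outdir, "binsize.txt"), "w") as out:
            out.write("%d\n" % int(binsize))
        b1 = f["pixels/bin1_id"][:]
        b2 = f["pixels/bin2_id"][:]
        cnt = f["pixels/count"][:]
        with open(os.path.join(outdir, "pixels.tsv"), "w") as out:
            out.write("bin1_id\tbin2_id\tcount\n")
            for i in range(len(b1)):
                out.write("%d\t%d\t%r\n" % (b1[i], b2[i], float(cnt[i])))


if __name__ == "__main__":
    if len(sys.argv) != 3:
        sys.stderr.write(__doc__)
        sys.exit(1)
    main(sys.argv[1], sys.argv[2])
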