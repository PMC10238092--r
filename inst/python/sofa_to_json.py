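"""Decode a SOFA (AES69) SimpleFreeFieldHRIR file to JSON.

SOFA files are netCDF-4, i.e. HDF5; h5py reads the underlying datasets
directly. Emits source positions (spherical, degrees), the sampling rate
and the IR array [measurement x receiver x sample].
"""
import json
import sys

import h5py
import numpy as np


def main(path, out):
    with h5py.File(path, "r") as f:
        ir = np.asarray(f["Data.IR"])
        fs = float(np.asarray(f["Data.SamplingRate"]).ravel()[0])
        pos = np.asarray(f["SourcePosition"])
    if ir.ndim != 3:
        raise SystemExit("Data.IR must be [M x R x N]")
    payload = {
        "sample_rate_hz": fs,
        "azimuth_deg": pos[:, 0].tolist(),
        "elevation_deg": pos[:, 1].tolist(),
        "ir": ir.tolist(),
    }
    with open(out, "w") as fh:
        json.dump(payload, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
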