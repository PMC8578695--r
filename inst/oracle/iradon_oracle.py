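# Independent filtered back projection reference (scikit-image iradon).
# Usage: python iradon_oracle.py SINO_CSV ANGLES_TXT OUT_CSV
# SINO_CSV: views x detector-bins matrix of line integrals in *pixel*
# units (physical line integrals divided by the detector bin spacing).
import sys

import numpy as np
from skimage.transform import iradon

sino = np.loadtxt(sys.argv[1], delimiter=",")
theta = np.atleast_1d(np.loadtxt(sys.argv[2]))
rec = iradon(sino.T, theta=theta, filter_name="ramp", circle=True,
             output_size=sino.shape[1])
np.savetxt(sys.argv[3], rec, delimiter=",")
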