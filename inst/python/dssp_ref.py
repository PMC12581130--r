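"""Independent DSSP reference: prints one secondary-structure line per frame
(H/E/-, pydssp 3-state convention via MDAnalysis) for a PDB file.

Usage: python dssp_ref.py structure.pdb
"""
import sys
import warnings

warnings.filterwarnings("ignore")

import MDAnalysis as mda
from MDAnalysis.analysis.dssp import DSSP

u = mda.Universe(sys.argv[1])
res = DSSP(u, guess_hydrogens=True).run()
for frame in res.results.dssp:
    print("".join(frame))
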