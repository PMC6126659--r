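# Default pipeline configuration for a SaBphP1-like photosensory core module.
#
# Residue ranges are 1-based inclusive in author numbering. The GAF-to-PHY
# boundary sits at the helical kink near residue 325; the sensory tongue is
# 435-485. The interface-helix ranges are the helix-3/helix-6 roles used for
# the bundle-axis offset angle; they match the synthetic-dimer generator's
# defaults and are meant to be overridden per structure for real depositions.
domains:
  PAS: [1, 115]
  GAF: [116, 325]
  PHY: [326, 516]
  tongue: [435, 485]
interface_helices:
  h3: [250, 269]
  h6: [280, 299]
# Conserved landmark motifs (X = any residue): the GAF-domain PASDIP motif
# (Asp208) and the PHY-domain PRXSF motif (Arg472/Ser474).
motifs:
  PASDIP: PASDIP
  PRXSF: PRXSF
# Optional crystallographic symmetry operator (12 numbers, row-major 3x3
# rotation then translation) used to build a dimer from a monomeric
# asymmetric unit, e.g. a two-fold about z:
# symmetry: [-1, 0, 0, 0, -1, 0, 0, 0, 1, 0, 0, 0]
cutoff_A: 5
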