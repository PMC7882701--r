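# Default sign conventions and output caps for the 13 stability predictors
# of the benchmark panel. These are EDITABLE PLACEHOLDERS chosen by the
# package authors: the benchmark publications do not state per-tool caps,
# and sign conventions should be checked against the actual tool output
# before analysing real data. sign: pos means the tool reports
# destabilizing variants with positive ddG; neg means negative.
# cap: maximum |ddG| the tool reports (null = uncapped).
FoldX5:   {sign: pos, cap: null}
INPS3D:   {sign: neg, cap: 10}
Rosetta:  {sign: pos, cap: null}
PoPMuSiC: {sign: pos, cap: 7}
IMutant:  {sign: neg, cap: null}
SDM:      {sign: neg, cap: null}
SDM2:     {sign: neg, cap: null}
mCSM:     {sign: neg, cap: null}
DUET:     {sign: neg, cap: null}
CUPSAT:   {sign: neg, cap: null}
MAESTRO:  {sign: neg, cap: null}
ENCoM:    {sign: neg, cap: null}
DynaMut:  {sign: neg, cap: null}
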