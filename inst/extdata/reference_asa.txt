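# residue max_asa_A2 (Gly-X-Gly tripeptide reference, Miller scale)
ALA 113
ARG 241
ASN 158
ASP 151
CYS 140
GLN 189
GLU 183
GLY 85
HIS 194
ILE 182
LEU 180
LYS 211
MET 204
PHE 218
PRO 143
SER 122
THR 146
TRP 259
TYR 229
VAL 160
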