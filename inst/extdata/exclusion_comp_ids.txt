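# Common ions, buffers and cryoprotectants excluded from ligand extraction.
# One chemical component identifier per line; '#' starts a comment.
HOH
WAT
DOD
GOL
EDO
PEG
PGE
PG4
1PE
MPD
DMS
ACT
ACE
ACY
FMT
SO4
PO4
NO3
CO3
CIT
TRS
EPE
MES
BME
DTT
IMD
NA
K
CL
BR
IOD
F
MG
CA
ZN
MN
FE
FE2
NI
CU
CO
CD
HG
LI
CS
SR
BA
AZI
SCN
NH4
BCT
EOH
IPA
MOH
POL
DIO
P6G
2PE
PE4
SPD
SPM
TLA
MLI
OXL
FLC
BTB
CAC
NO2
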