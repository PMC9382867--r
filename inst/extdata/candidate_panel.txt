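# Candidate genes: monogenic bone disorders in which atypical femur
# fractures have been reported (hypophosphatasia, osteogenesis imperfecta,
# pycnodysostosis, X-linked hypophosphatemia, osteopetrosis, osteoporosis
# pseudoglioma syndrome, X-linked osteoporosis).
ALPL
COL1A1
COL1A2
CRTAP
LEPRE1
PPIB
SERPINH1
FKBP10
PLOD2
SP7
CTSK
PHEX
TCIRG1
CLCN7
OSTM1
PLEKHM1
SNX10
TNFSF11
TNFRSF11A
CA2
LRP5
PLS3
# Genes from prior AFF sequencing and candidate-gene studies (the published
# candidate list's second part is not printed in full; these are the members
# named in the study text).
GGPS1
CYP1A1
TMEM25
ENPP1
FGF23
CYP27B1
CYP3A4
SLC34A3
CYP2R1
ATRAID
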