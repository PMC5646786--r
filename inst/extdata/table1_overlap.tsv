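symbol	overlapping_species
AMBRA1	horse
BRAF	cat;horse
CACNA1D	horse
COA5	dog
COL11A1	dog
COQ10B	dog
DLGAP1	horse
ERBB4	cattle
FAM172A	cattle;dog
GGT7	dog
GRIA1	cat
GRIK3	dog;cattle
HSD3B7	cat
HSPD1	dog
HSPE1	dog
ITGA9	cat
LRP1B	cattle
LYST	dog
MOB4	dog
MYLK3	cat
NCOA6	dog
NEK4	cat
NT5DC2	horse
NTM	horse
PLAC8L1	cat;cattle
PPAP2A	cat
PPAPDC1B	cat
PRR11	cat
PVRL3	cattle
RFTN2	dog
RNPC3	cat;dog
SF3B1	dog
SKA2	dog
SNRPD1	cattle
STAB1	horse
SYTL1	cat
TAS2R16	cattle
TEX14	cat
TP53BP1	cat
ZMYND10	cat
ZNF521	cattle
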