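raw	canonical
PPAP2A	PLPP1
PPAPDC1B	PLPP5
PVRL3	NECTIN3
HER4	ERBB4
MKL1	MRTFA
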