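province,region
P01,eastern
P02,central
P03,western
P04,eastern
P05,central
P06,western
P07,eastern
P08,central
P09,western
P10,eastern
P11,central
P12,western
P13,eastern
P14,central
P15,western
P16,eastern
P17,central
P18,western
P19,eastern
P20,central
P21,western
P22,eastern
P23,central
P24,western
P25,eastern
P26,central
P27,western
P28,eastern
P29,central
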