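>BIP1 S. pombe BIP1 mRNA Ire1 cleavage-site hairpin (31 nt)
CGCGAGAUAACUGGUGCUUUGUUAUCUCGCG
>SPAC4G9.15 S. pombe SPAC4G9.15 mRNA Ire1 cleavage-site hairpin (29 nt)
CCACCACCGAGUAUGCUACUCGGUGGUGG
>HAC1_3SS S. cerevisiae HAC1 mRNA 3' splice-site hairpin (29 nt)
GCGCGGACUGUCCGAAGCGCAGUCCGCGC
>XBP1 human XBP1 mRNA 3' splice-site hairpin (21 nt)
UGCACCUCUGCAGCAGGUGCA
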