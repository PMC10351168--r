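# Synthetic example of the binding predictor's tabular output format.
# Fabricated values for parser testing only; not produced by any real run.
-----------------------------------------------------------------------------------
 Pos         HLA        Peptide      Core Of Gp Gl Ip Il        Icore     Identity  Score_EL %Rank_EL  Score_BA %Rank_BA   Aff(nM) BindLevel
-----------------------------------------------------------------------------------
   1 HLA-A*02:01     KLWQRTNEL KLWQRTNEL  0  0  0  0  0    KLWQRTNEL      PEPLIST  0.843100   0.1200  0.712000   0.3500     42.70 <= SB
   2 HLA-A*02:01     GGGGSLRWM GGGGSLRWM  0  0  0  0  0    GGGGSLRWM      PEPLIST  0.012000  18.0000  0.101000  12.5000   8123.00
   3 HLA-A*02:01     AVFDRKSDA AVFDRKSDA  0  0  0  0  0    AVFDRKSDA      PEPLIST  0.221000   1.9000  0.402000   1.8000    498.00 <= WB
-----------------------------------------------------------------------------------
Protein PEPLIST. Allele HLA-A*02:01. Number of high binders 1.
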