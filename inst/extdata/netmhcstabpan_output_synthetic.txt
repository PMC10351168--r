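# Synthetic example of the stability predictor's tabular output format.
# Fabricated values for parser testing only; not produced by any real run.
-----------------------------------------------------------------------------------
 Pos         HLA        Peptide     Identity    Pred  Thalf(h) %Rank_Stab
-----------------------------------------------------------------------------------
   1 HLA-A*02:01     KLWQRTNEL      PEPLIST  0.5210      3.25       0.80
   2 HLA-A*02:01     GGGGSLRWM      PEPLIST  0.0150      0.08      42.00
-----------------------------------------------------------------------------------
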