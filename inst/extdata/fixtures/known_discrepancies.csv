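fixture,lorica_id,printed_total_pg,recomputed_total_pg,note
table2,K07,180,182,printed components sum to 182
table3_atlantic,NA_CALC,5008,5020,identified mean lith counts give 5020
table3_atlantic,NA_COCC,6966,6828,identified mean lith counts give 6828
table3_atlantic,NA_DIAT,1228,1062,identified liths 1028 pg CaCO3 plus 34 pg silica
table3_atlantic,NA_OTH,1276,3208,identified mean lith counts give 3208
table3_sots,SOTS,10540,10492,identified mean lith counts give 10492
table4,T02,1058,886,printed components sum to 886
table4,T03,704,713,printed components sum to 713
table4,C01,1472,1478,printed components sum to 1478
table5,D_SOTS,19922,19220,Calcidiscus mean count only; other taxa occurrence-only
table5,D_IND,3248,2587,identified components give 2587
table5,D_TONGA,2428,331,identified components give 331; printed value equals the stated pooled tropical mean
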