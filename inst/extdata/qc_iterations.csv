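iteration,n_samples,match_pct,tp,fn,fp,tp_tn_pct,fn_pct,fp_pct
1,58,81,4,7,0,88,12,0
1.1,58,NA,NA,NA,NA,NA,NA,NA
2,64,96.87,0,2,0,97,2,0
3,512,78.1,66,12,20,93,3,4
3.5,1024,74.4,172,30,55,91,3,5
4.2,160,84.4,1,16,8,85,10,5
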