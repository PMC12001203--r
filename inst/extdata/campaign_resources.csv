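iteration,n_targets,manual_days_per_target,auto_days_total,manual_columns_per_target,auto_columns_total,manual_solvent_per_target_ml,auto_solvent_per_target_ml
1,58,3,3,1,1,1000,5
1.1,58,3,3,1,1,1000,5
2,64,1,2,1,1,1000,5
3,512,5,4,2,2,2500,10
3.5,1024,5,4,2,2,2500,10
4.2,160,8,4,3,3,4500,15
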