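quantity,value
residual_ss,11.3
residual_df,7
pure_error_ss,2.8
pure_error_df,4
total_ss,749.06
total_df,16
vl_ug_kg,50
confirmation_mean,42.8
confirmation_rsd_pct,0.9
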