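analysis,te_rd_pp,cde_rd_pp,pct_mediation_printed
primary,7.09,6.08,14.22
job_loss,7.42,6.30,15.10
job_gain,-6.35,-5.79,8.77
older_41_64,6.96,5.71,17.97
younger_25_40,7.72,7.10,7.99
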