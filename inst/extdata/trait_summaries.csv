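variable,sex,group,mean,se,n
individual_F,female,single,0.012,0.009,51
individual_F,male,single,0.037,0.017,51
individual_F,female,double,0.002,0.018,22
individual_F,male,double,0.004,0.024,22
heterozygosity_Hs,female,single,0.725,0.018,51
heterozygosity_Hs,male,single,0.712,0.020,51
heterozygosity_Hs,female,double,0.790,0.039,22
heterozygosity_Hs,male,double,0.807,0.030,22
stripe_width,male,single,9.525,0.256,51
stripe_width,male,double,10.838,0.561,22
tarsus_length,female,single,21.298,0.139,51
tarsus_length,male,single,21.690,0.188,51
tarsus_length,female,double,21.553,0.262,22
tarsus_length,male,double,21.216,0.264,22
repertoire_size,male,single,3.55,0.174,42
repertoire_size,male,double,3.95,0.381,21
relatedness,pair,single,0.070,0.030,51
relatedness,pair,double,-0.096,0.037,22
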