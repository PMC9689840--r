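comparison,parameter,n,mean_error,sd,rmse_printed
rater1_vs_rater2a_preop,mFAmTA,95,0.09,1.11,1.11
rater1_vs_rater2a_preop,mLDTA,95,-0.46,2.0,2.0
rater1_vs_rater2a_preop,FSAmTA,95,0.1,1.03,1.03
ai_vs_rater1_preop,mLDTA,94,0.97,1.98,2.2
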