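label,mesor,amplitude,period,acrophase_clock,dsp_prob,sleep_onset_mean,sleep_onset_sd,meq_mean,meq_sd,n_subjects
cluster1,34.29,1.02,25.75,2.6667,0.46,0.2,63.5,12.71,4.0,100
cluster2,33.46,1.38,25.76,2.5667,0.68,2.05,84.0,12.43,3.9,130
cluster3,32.80,2.09,25.33,2.0333,0.37,0.8,70.9,14.38,4.0,51
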