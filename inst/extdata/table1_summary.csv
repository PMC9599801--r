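variable,type,mci_a,mci_b,nc_a,nc_b,n1,n2,printed_statistic,printed_p,reproducible
gender,chisq,13,17,16,14,30,30,0.601,0.438,TRUE
age,t,67.17,4.12,67.73,4.40,30,30,-0.515,0.609,FALSE
education,t,10.63,3.75,10.23,3.23,30,30,0.443,0.660,TRUE
moca,t,22.08,2.24,28.08,1.41,30,30,-11.350,NA,FALSE
duration,t,14.23,7.80,15.43,8.34,30,30,-0.576,0.567,TRUE
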