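# Benchmark hPDC expansion study: accumulated lactate divided by endpoint
# cell number and by the 120 h culture span, mean +/- SD over triplicates,
# in units of 1e-7 mM per cell per hour.
condition,donor,mean,sd
1,1,6.71,0.65
1,2,11.49,2.84
1,3,10.07,1.55
2,1,6.16,0.33
2,2,6.29,0.65
2,3,7.83,0.67
3,1,7.27,0.66
3,2,7.26,1.65
3,3,8.18,1.38
4,1,11.78,3.93
4,2,13.35,0.88
4,3,12.09,4.21
5,1,6.14,0.99
5,2,7.09,0.89
5,3,7.06,1.11
6,1,5.27,0.40
6,2,5.40,0.69
6,3,6.44,0.65
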