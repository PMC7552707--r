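# Benchmark hPDC expansion study: medium-use efficiency (harvested cells per
# total medium used, seeding fill included), mean +/- SD over triplicates,
# in units of 1e4 cells per mL.
condition,donor,mean,sd
1,1,7.79,0.71
1,2,4.61,1.15
1,3,6.91,0.93
2,1,7.53,0.48
2,2,7.29,0.60
2,3,7.79,0.55
3,1,7.06,0.45
3,2,6.88,1.55
3,3,8.21,1.15
4,1,6.85,1.79
4,2,4.67,0.29
4,3,7.86,2.70
5,1,6.64,0.63
5,2,5.38,0.61
5,3,6.29,0.88
6,1,4.73,0.41
6,2,4.48,0.51
6,3,4.17,0.44
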