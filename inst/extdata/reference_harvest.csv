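# Benchmark hPDC expansion study: cells harvested after 120 h, mean +/- SD
# over triplicates, in units of 1e5 cells.
condition,donor,mean,sd
1,1,1.48,0.13
1,2,0.88,0.22
1,3,1.31,0.18
2,1,1.69,0.11
2,2,1.63,0.13
2,3,1.75,0.12
3,1,1.48,0.10
3,2,1.45,0.33
3,3,1.73,0.24
4,1,0.96,0.25
4,2,0.65,0.04
4,3,1.10,0.38
5,1,1.99,0.19
5,2,1.61,0.18
5,3,1.89,0.26
6,1,2.37,0.21
6,2,2.24,0.25
6,3,2.08,0.22
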