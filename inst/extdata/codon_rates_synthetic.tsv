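codon	rate_per_s
AAA	4.836734668
AAC	12.66755874
AAG	2.032176022
AAT	11.27527078
ACA	21.17930872
ACC	3.226444414
ACG	6.156291009
ACT	10.57806049
AGA	2.897630914
AGC	6.673973764
AGG	3.22572903
AGT	2.816405917
ATA	18.87230683
ATC	8.490032861
ATG	10.47413116
ATT	11.57332354
CAA	14.36670022
CAC	13.37232647
CAG	3.122509059
CAT	6.5817175
CCA	6.710012718
CCC	8.060391802
CCG	25.15021414
CCT	10.3311181
CGA	10.01577934
CGC	4.747394798
CGG	5.155406247
CGT	6.53186764
CTA	1.518492755
CTC	24.97864389
CTG	5.668276547
CTT	6.513167078
GAA	6.15812233
GAC	1.864980467
GAG	18.20247437
GAT	4.7387785
GCA	4.381324284
GCC	8.646805476
GCG	4.263445678
GCT	17.77273387
GGA	1.657105231
GGC	28.48039397
GGG	9.081251915
GGT	40.89486085
GTA	6.64064871
GTC	22.7670211
GTG	3.012014986
GTT	3.898001787
TAC	16.62934469
TAT	13.71302592
TCA	12.00117652
TCC	3.122069683
TCG	2.228979647
TCT	11.43266374
TGC	5.762149194
TGG	10.45021678
TGT	16.24667738
TTA	17.88035268
TTC	1.270139084
TTG	13.11579193
TTT	13.88805205
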