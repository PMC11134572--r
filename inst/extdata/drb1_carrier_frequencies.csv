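# Aggregated HLA-DRB1 carrier frequencies (% of individuals carrying the allele)
# for Japanese and Caucasian reference populations; alleles >1% in at least one
# population. Percent scale, two decimals.
allele,Japanese,Caucasian
DRB1*01:01,13.51,15.02
DRB1*01:03,0.00,1.96
DRB1*01:04,0.00,4.02
DRB1*03:01,0.72,29.04
DRB1*04:01,2.28,7.82
DRB1*04:04,12.23,8.41
DRB1*04:05,25.70,6.54
DRB1*04:08,0.92,1.94
DRB1*04:10,3.80,0.09
DRB1*07:01,0.41,24.05
DRB1*08:01,16.78,3.98
DRB1*08:02,7.38,0.34
DRB1*08:73,3.02,0.01
DRB1*09:01,28.77,0.71
DRB1*11:01,4.00,11.47
DRB1*11:02,0.20,6.60
DRB1*11:04,4.09,8.29
DRB1*11:58,2.40,0.03
DRB1*12:01,8.93,2.58
DRB1*13:01,1.22,11.39
DRB1*13:02,12.49,7.28
DRB1*13:03,0.00,2.58
DRB1*14:01,5.10,4.83
DRB1*15:01,13.99,16.04
DRB1*15:02,22.89,1.86
DRB1*16:01,1.53,6.98
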