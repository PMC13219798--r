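"sample_id","latitude","sst","sss","po4","ta","dic","d13c_dic","mld","sst_anomaly"
"S01",60,5.294590823,34.0474553,1.405145948,2277.151142,2107.697583,1.008676147,293.1910193,0.9
"S02",48.75,11.16211845,34.6992321,0.8097921387,2314.244921,2091.931456,1.537421551,176.32923,0.8625
"S03",37.5,16.3502262,35.7204025,0.4462348492,2370.006129,2105.972693,1.783386758,122.3353031,0.825
"S04",26.25,20.92510793,36.42477356,0.1941499762,2384.679479,2087.442079,1.486378948,61.79228753,0.7875
"S05",15,25.03492954,35.70739841,0.214123711,2403.131213,2083.82567,1.432154309,48.44153813,0.75
"S06",3.75,27.53614395,35.29448826,0.2457687216,2398.049349,2068.200956,1.204793017,29.93777208,0.7125
"S07",-7.5,26.66602523,35.44800027,0.3132340315,2402.042851,2086.455169,1.221428699,47.42102413,0.675
"S08",-18.75,23.53130134,36.24943369,0.1345620425,2379.13817,2086.993344,1.306226753,53.34168023,0.6375
"S09",-30,19.17758609,36.2074069,0.2811511876,2375.114262,2105.319252,1.571652559,83.11340541,0.6
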