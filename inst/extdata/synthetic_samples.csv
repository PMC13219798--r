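"sample_id","latitude","longitude","depth","age"
"S01",60,-23.88709241,2451.373916,1732.667508
"S02",48.75,-20.00399181,2463.947782,2488.900907
"S03",37.5,-17.79827796,1629.337316,1559.999072
"S04",26.25,-17.07500545,1523.874415,1021.523925
"S05",15,-25.82042938,2340.763209,1655.515255
"S06",3.75,-32.77184402,2719.455251,1258.095498
"S07",-7.5,-32.6320965,1990.369413,1254.46384
"S08",-18.75,-25.84516564,1658.87513,1385.548586
"S09",-30,-20.79865525,2149.639593,2344.767581
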