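" ","Area","Major","Minor","Angle"
1,423.32,31.869,23.216,60
2,41.36,9.977,7.257,92.7
3,49.19,17.408,7.914,133.9
4,10.91,20.466,3.727,111.4
5,100.79,17.843,11.328,112.7
6,33.54,13.136,6.535,39.1
7,100.32,34.673,11.302,39
8,128.74,13.227,12.803,70
9,179.1,46.998,15.101,169.6
10,34.61,13.483,6.638,173.3
11,105.41,30.63,11.585,133.2
12,11.42,55.205,3.814,132
13,29.03,6.084,6.08,96.4
14,27.16,11.844,5.881,0.4
15,5.69,12.924,2.692,109.6
16,65.96,20.504,9.164,150.6
17,78.16,11.805,9.976,135.3
18,6.35,2.844,2.844,81.5
19,8.23,3.237,3.237,96.4
20,30.76,30.911,6.258,96.7
21,16.2,11.647,4.541,0.2
22,18.16,4.808,4.808,64
23,28.26,12.628,5.999,110.2
24,269.62,29.016,18.528,149.2
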