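subject,duration_h,n_seizures,false_detections,fd_per_hour
1,24,1,5,0.2
2,24,7,10,0.4
3,21.3,44,18,0.8
4,24.1,114,28,1.2
5,24,13,10,0.4
6,19.7,120,10,0.5
7,24,1,6,0.3
8,24.1,72,12,0.5
9,24.8,33,10,0.4
10,34.4,6,9,0.3
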