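plant_id,trial1_deg,trial2_deg,predicted_deg
1,100,106,102.7
2,88,92,91.2
3,92,91,95.2
4,76,75,72.7
5,93,100,101.5
6,77,71,74.6
7,79,73,77.4
8,91,99,100.3
9,79,87,77
10,96,105,101
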