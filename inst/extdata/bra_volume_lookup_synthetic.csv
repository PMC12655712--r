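band,cup,volume_cm3
8,AA,200
8,A,250
8,B,300
8,C,350
8,D,400
8,DD,450
8,E,500
8,F,550
8,G,600
10,AA,250
10,A,312.5
10,B,375
10,C,437.5
10,D,500
10,DD,562.5
10,E,625
10,F,687.5
10,G,750
12,AA,300
12,A,375
12,B,450
12,C,525
12,D,600
12,DD,675
12,E,750
12,F,825
12,G,900
14,AA,350
14,A,437.5
14,B,525
14,C,612.5
14,D,700
14,DD,787.5
14,E,875
14,F,962.5
14,G,1050
16,AA,400
16,A,500
16,B,600
16,C,700
16,D,800
16,DD,900
16,E,1000
16,F,1100
16,G,1200
18,AA,450
18,A,562.5
18,B,675
18,C,787.5
18,D,900
18,DD,1012.5
18,E,1125
18,F,1237.5
18,G,1350
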