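design,alt_cluster,ref_cluster,n
B,1,1,11
B,1,2,12
B,1,3,0
B,1,4,1
B,2,1,5
B,2,2,29
B,2,3,8
B,2,4,0
B,3,1,1
B,3,2,9
B,3,3,9
B,3,4,13
B,4,1,0
B,4,2,13
B,4,3,6
B,4,4,12
C,1,1,15
C,1,2,3
C,1,3,0
C,1,4,0
C,2,1,0
C,2,2,23
C,2,3,2
C,2,4,5
C,3,1,0
C,3,2,33
C,3,3,7
C,3,4,0
C,4,1,2
C,4,2,4
C,4,3,14
C,4,4,21
D,1,1,14
D,1,2,4
D,1,3,0
D,1,4,0
D,2,1,1
D,2,2,52
D,2,3,8
D,2,4,2
D,3,1,0
D,3,2,1
D,3,3,8
D,3,4,2
D,4,1,2
D,4,2,6
D,4,3,7
D,4,4,22
E,1,1,16
E,1,2,15
E,1,3,0
E,1,4,0
E,2,1,1
E,2,2,45
E,2,3,7
E,2,4,3
E,3,1,0
E,3,2,1
E,3,3,13
E,3,4,0
E,4,1,0
E,4,2,2
E,4,3,3
E,4,4,23
F,1,1,15
F,1,2,1
F,1,3,1
F,1,4,0
F,2,1,0
F,2,2,47
F,2,3,3
F,2,4,1
F,3,1,0
F,3,2,7
F,3,3,8
F,3,4,1
F,4,1,2
F,4,2,8
F,4,3,11
F,4,4,24
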