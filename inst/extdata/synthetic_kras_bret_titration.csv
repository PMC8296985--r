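well,condition,ad_ratio,rfu,em410,em515,replicate
A1_R1,donor_acceptor,1,21419,1e+05,14085.8,1
A1_R2,donor_acceptor,1,20366.4,1e+05,14002.4,2
A1_R3,donor_acceptor,1,20408.4,1e+05,13950.9,3
A2_R1,donor_acceptor,2,48532.7,1e+05,18130.3,1
A2_R2,donor_acceptor,2,49778.5,1e+05,18294.8,2
A2_R3,donor_acceptor,2,48033.9,1e+05,18459.5,3
A4_R1,donor_acceptor,4,79297.6,1e+05,21533.7,1
A4_R2,donor_acceptor,4,84435.3,1e+05,22244.8,2
A4_R3,donor_acceptor,4,83800.5,1e+05,21407.9,3
A8_R1,donor_acceptor,8,150471.7,1e+05,27416.8,1
A8_R2,donor_acceptor,8,167413.5,1e+05,27269.9,2
A8_R3,donor_acceptor,8,168545,1e+05,28396.7,3
D_R1,donor_only,0,0,1e+05,10191.3,1
D_R2,donor_only,0,0,1e+05,9957,2
D_R3,donor_only,0,0,1e+05,9974.3,3
D_R4,donor_only,0,0,1e+05,9825.2,4
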