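# gene=DQB1
# positions=1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23,24,25,26,27,28,29,30
# synthetic alignment fixture: invented sequences, not IPD-IMGT/HLA data
DQB1*02:01	RDSPEDFVFQKGMCYFTNGTERVRLVTRYA
DQB1*03:01	--------Y-------------D-------
DQB1*03:02	------------------------------
DQB1*05:01	--------L---------------------
DQB1*06:02	--------Y---------------------
DQB1*06:03	--------L-------------D------*
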