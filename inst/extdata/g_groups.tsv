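# name=g_groups
# resolution=2
A*01:01:01G	A*01:01
A*02:01:01G	A*02:01
A*03:01:01G	A*03:01
B*07:02:01G	B*07:02
B*44:02:01G	B*44:02
C*07:01:01G	C*07:01
C*07:02:01G	C*07:02
DQB1*03:01:01G	DQB1*03:01
DQB1*06:02:01G	DQB1*06:02
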