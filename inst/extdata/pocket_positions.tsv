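region	position
ARD	1
ARD	2
ARD	3
ARD	4
ARD	5
ARD	6
ARD	7
ARD	8
ARD	9
ARD	10
ARD	11
ARD	12
ARD	13
ARD	14
ARD	15
ARD	16
ARD	17
ARD	18
ARD	19
ARD	20
ARD	21
ARD	22
ARD	23
ARD	24
ARD	25
ARD	26
ARD	27
ARD	28
ARD	29
ARD	30
ARD	31
ARD	32
ARD	33
ARD	34
ARD	35
ARD	36
ARD	37
ARD	38
ARD	39
ARD	40
ARD	41
ARD	42
ARD	43
ARD	44
ARD	45
ARD	46
ARD	47
ARD	48
ARD	49
ARD	50
ARD	51
ARD	52
ARD	53
ARD	54
ARD	55
ARD	56
ARD	57
ARD	58
ARD	59
ARD	60
ARD	61
ARD	62
ARD	63
ARD	64
ARD	65
ARD	66
ARD	67
ARD	68
ARD	69
ARD	70
ARD	71
ARD	72
ARD	73
ARD	74
ARD	75
ARD	76
ARD	77
ARD	78
ARD	79
ARD	80
ARD	81
ARD	82
ARD	83
ARD	84
ARD	85
ARD	86
ARD	87
ARD	88
ARD	89
ARD	90
ARD	91
ARD	92
ARD	93
ARD	94
ARD	95
ARD	96
ARD	97
ARD	98
ARD	99
ARD	100
ARD	101
ARD	102
ARD	103
ARD	104
ARD	105
ARD	106
ARD	107
ARD	108
ARD	109
ARD	110
ARD	111
ARD	112
ARD	113
ARD	114
ARD	115
ARD	116
ARD	117
ARD	118
ARD	119
ARD	120
ARD	121
ARD	122
ARD	123
ARD	124
ARD	125
ARD	126
ARD	127
ARD	128
ARD	129
ARD	130
ARD	131
ARD	132
ARD	133
ARD	134
ARD	135
ARD	136
ARD	137
ARD	138
ARD	139
ARD	140
ARD	141
ARD	142
ARD	143
ARD	144
ARD	145
ARD	146
ARD	147
ARD	148
ARD	149
ARD	150
ARD	151
ARD	152
ARD	153
ARD	154
ARD	155
ARD	156
ARD	157
ARD	158
ARD	159
ARD	160
ARD	161
ARD	162
ARD	163
ARD	164
ARD	165
ARD	166
ARD	167
ARD	168
ARD	169
ARD	170
ARD	171
ARD	172
ARD	173
ARD	174
ARD	175
ARD	176
ARD	177
ARD	178
ARD	179
ARD	180
ARD	181
ARD	182
B_pocket	7
B_pocket	9
B_pocket	24
B_pocket	25
B_pocket	34
B_pocket	45
B_pocket	63
B_pocket	66
B_pocket	67
B_pocket	70
B_pocket	99
F_pocket	77
F_pocket	80
F_pocket	81
F_pocket	84
F_pocket	95
F_pocket	116
F_pocket	123
F_pocket	143
F_pocket	146
F_pocket	147
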