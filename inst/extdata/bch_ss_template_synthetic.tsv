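name	kind	start	end
loop0	loop	1	7
betaN	strand	8	14
loop1	loop	15	21
alpha1	helix	22	42
loop2	loop	43	49
beta1	strand	50	56
loop3	loop	57	63
alpha2	helix	64	84
loop4	loop	85	91
beta2	strand	92	98
loop5	loop	99	105
alpha3	helix	106	126
loop6	loop	127	133
beta3	strand	134	140
loop7	loop	141	149
betaC	strand	150	156
loopC	loop	157	173
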