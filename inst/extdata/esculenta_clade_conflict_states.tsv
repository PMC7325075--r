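species	MAT1-1-1	MAT1-2-1	F1	IGS
M. americana	X	X	X	O
M. clivicola	C	X	X	X
M. dunensis	X	C	C	C
M. esculenta	X	X	C	C
M. galilaea	X	X	C	C
M. palazonii	X	X	O	C
M. steppicola	O	O	N	N
M. yangii	C	X	C	C
M. yishuica	X	X	X	X
Mes-6	X	C	C	C
Mes-9	C	C	C	C
Mes-10	X	X	O	O
Mes-15	X	X	X	X
Mes-19	X	X	C	C
Mes-20	C	C	C	C
Mes-21	X	C	C	C
Mes-22	C	C	X	C
Mes-23	C	C	C	C
Mes-24	O	O	N	N
Mes-25	X	X	C	O
Mes-26	X	X	O	C
Mes-27	X	X	X	O
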