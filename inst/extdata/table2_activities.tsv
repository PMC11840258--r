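peptide	E_coli	C_rodentium	S_nepalensis	E_fecalis
Defa4	781	314	352	135
Defa17	438	402	332	395
Defa24	122	77	8	23
Defa17-24	312	361	359	193
Defa30	186	107	6	52
Defa31	397	314	437	189
Defa30-31	140	132	125	49
Defa35	262	260	77	127
Defa30b	186	107	6	52
Defa35-30	626	774	372	269
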