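#EQTS v1
#X=a,b,c,d,e
a	b	c	d	gamma	nu_ab	nu_cd
a	b	c	d	1	0	0
a	b	c	e	0	0	0
a	b	d	e	0	0	0
a	e	c	d	1	0	0
b	e	c	d	1	0	0
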