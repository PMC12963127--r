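#EQTS v1
#X=a,b,c,d,e,f,g
a	b	c	d	gamma	nu_ab	nu_cd
a	b	c	d	0	0	1
a	b	c	e	0	0	1
a	b	c	f	0	0	1
a	b	c	g	0	0	1
a	b	d	e	1	0	0
a	b	d	f	0	0	1
a	b	d	g	0	0	1
a	b	e	f	0	0	1
a	b	e	g	0	0	1
a	b	f	g	0	0	1
a	c	d	e	0	1	0
a	c	d	g	0	1	1
a	c	e	g	0	1	1
a	f	c	d	0	1	1
a	f	c	e	0	1	1
a	f	c	g	0	1	1
a	f	d	e	0	1	0
a	f	d	g	0	1	1
a	f	e	g	0	1	1
a	g	d	e	0	1	0
b	c	d	e	0	1	0
b	c	d	g	0	1	1
b	c	e	g	0	1	1
b	f	c	d	0	1	1
b	f	c	e	0	1	1
b	f	c	g	0	1	1
b	f	d	e	0	1	0
b	f	d	g	0	1	1
b	f	e	g	0	1	1
b	g	d	e	0	1	0
c	f	d	e	0	1	0
c	f	d	g	0	1	1
c	f	e	g	0	1	1
c	g	d	e	0	1	0
d	e	f	g	0	0	1
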