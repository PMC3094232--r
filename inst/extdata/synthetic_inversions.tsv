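species	arm	region_id	start_mb	end_mb
gambiae_like	2R	j	2.0000	14.5000
gambiae_like	2R	b	18.0000	26.2000
gambiae_like	2R	d	24.0000	30.0000
gambiae_like	2R	c	26.8000	31.5000
gambiae_like	2R	u	31.8000	35.8000
stephensi_like	2R	e	4.0000	10.0000
stephensi_like	2R	f	14.0000	20.0000
stephensi_like	2R	g	25.0000	32.0000
stephensi_like	2R	h	38.0000	42.3000
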