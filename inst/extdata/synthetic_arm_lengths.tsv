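species	arm	length_mb
gambiae_like	2R	61.5
stephensi_like	2R	55
spA	2R	60.9
spB	2R	60.9
spC	2R	60.9
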