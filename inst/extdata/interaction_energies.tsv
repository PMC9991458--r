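# Actin-tropomyosin interaction energies (kcal/mol) by regulatory state.
# B (blocked) includes tropomyosin-troponin I contacts; C (closed) is
# tropomyosin-actin only. Mean and SD over 500 structural-simulation frames.
genotype	state	mean	sd	n_frames
wt	B	-5108.7	280.9	500
wt	C	-3895.4	236.9	500
s215l	B	-4581.3	232.9	500
s215l	C	-4426.2	206.2	500
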