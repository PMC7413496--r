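fill_mode	depth_um	fwhm_xy_um	fwhm_z_um	n_beads
overfill	100	0.41	2.16	15
overfill	200	0.40	2.33	11
overfill	300	0.53	4.14	11
underfill	100	0.44	2.68	10
underfill	200	0.50	2.87	10
underfill	300	0.58	4.51	12
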