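target_id	group	mean_dct	sd_dct	n
miR-21-5p	tumor	-1.78	0.12	18
miR-21-5p	adjacent	0.37	0.08	18
miR-21-5p	normal	1.89	0.11	18
miR-196a-5p	tumor	0.47	0.09	18
miR-196a-5p	adjacent	1.83	0.06	18
miR-196a-5p	normal	3.44	0.04	18
miR-218-5p	tumor	1.25	0.14	18
miR-218-5p	adjacent	0.35	0.05	18
miR-218-5p	normal	-1.05	0.09	18
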