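form_id	parameter	value	unit	ref_temp_c	delta_h_kj_mol	source
II	kcat_C	13.1	1/s	25	67.4	example (synthetic, field-plausible)
II	K_C	240	uM	25	48.6	example (synthetic, field-plausible)
II	K_O	1280	uM	25	21.2	example (synthetic, field-plausible)
II	S_CO	10.3	dimensionless	25	NA	example (synthetic, field-plausible)
II	kcat_O	NA	1/s	25	55.3	example (synthetic, field-plausible)
IAc	kcat_C	2.98	1/s	30	NA	example (turnover as reported for a carboxysomal IA at 30 C)
IAc	K_C	42	uM	25	NA	example (synthetic, field-plausible)
IAc	K_O	610	uM	25	NA	example (synthetic, field-plausible)
IAc	S_CO	47	dimensionless	25	NA	example (synthetic, field-plausible)
IAq	kcat_C	1.97	1/s	30	NA	example (synthetic, field-plausible)
IAq	K_C	74	uM	25	NA	example (synthetic, field-plausible)
IAq	K_O	520	uM	25	NA	example (synthetic, field-plausible)
IAq	S_CO	41	dimensionless	25	NA	example (synthetic, field-plausible)
IA	kcat_C	NA	1/s	NA	47.2	form-IA-level enthalpy shared by IAc and IAq
IA	K_C	NA	uM	NA	33.0	form-IA-level enthalpy shared by IAc and IAq
IA	K_O	NA	uM	NA	14.5	form-IA-level enthalpy shared by IAc and IAq
IA	kcat_O	NA	1/s	NA	38.1	form-IA-level enthalpy shared by IAc and IAq
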