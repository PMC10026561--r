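id	source_protein	binder_class	core_sequence
M1	LAT	PLCG1	YLVV
M2	synthetic placeholder	GRB2	NA
M3	synthetic placeholder	GADS	NA
M4	synthetic placeholder	PI3K	NA
M5	synthetic placeholder	VAV1	NA
M6	LAIR1	SHP1	ITYAAV
M7	synthetic placeholder	LCK	NA
M8	synthetic placeholder	PELLINO	NA
M9	CD40	TRAF	PQVE
M10	synthetic placeholder	TRAF	NA
M11	synthetic placeholder	TRAF	NA
M12	synthetic placeholder	OTHER	NA
M13	spacer	SPACER	NA
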