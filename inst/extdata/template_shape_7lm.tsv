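landmark	x_mm	y_mm
mouth	0.0	0.0
post_dorsal_skull	6.0	2.1
ant_dorsal_fin	12.0	2.5
caudal_fin	20.0	0.2
ant_anal_fin	12.5	-2.6
ventral_surface	6.5	-3.9
vent_ant_skull	2.0	-3.2
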