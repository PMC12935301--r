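# CHD4 (Q14839, 1912 aa) domain architecture as residue intervals.
# role: domain = top-level non-overlapping region; subdomain = nested within
# `parent` (subdomain overlaps are permitted and all reported); composite =
# named union/span used for grouping, never the most-specific assignment.
# The HMG box-like interval is approximate: its length (82 aa) is
# established but precise printed boundaries are not; the interval below
# contains residue M202, which is asserted to lie within the HMG box.
name	parent	start	end	role	note
N_terminal		1	354	domain	IDR1/HMG/IDR2/APR-containing N-terminal region
HMG	N_terminal	145	226	subdomain	82-aa HMG box-like domain; boundaries approximate
PHD1		363	410	domain	plant homeodomain 1
PHD2		442	482	domain	plant homeodomain 2
CD1		522	579	domain	chromodomain 1
CD2		615	676	domain	chromodomain 2
ATPase		731	915	domain	ATPase lobe of the SNF2-family motor
helicase		1047	1192	domain	helicase lobe of the SNF2-family motor
C_terminal		1230	1912	domain	CTD1/CTD2-containing C-terminal region
C1a	C_terminal	1230	1380	subdomain	CTD1 subregion with autoinhibitory role
C1b	C_terminal	1400	1540	subdomain	CTD1 subregion (SANT-SLIDE part)
disordered_1	C_terminal	1310	1400	subdomain	predicted disordered linker
disordered_2	C_terminal	1540	1699	subdomain	predicted disordered linker
C2a	C_terminal	1700	1800	subdomain	CTD2 subregion (SANT-SLIDE part)
C2b	C_terminal	1800	1912	subdomain	CTD2 subregion
APR2	C2a	1735	1742	subdomain	aggregation-prone region YWLLAGII
ATPase_motor_region		731	1192	composite	ATPase + inter-lobe linker + helicase
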