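# CHD4 study cohort: 36 variants (33 missense, 1 splice donor, 1 in-frame
# duplication, 1 in-frame deletion) in patients with rare diseases and
# cardiovascular anomalies, transcribed from the source study's printed
# variant table. Scores are MetaRNN / PolyPhen-2 / AlphaMissense / REVEL as
# printed; `evidence` is the "+"-separated ACMG criteria string; `clinvar`
# uses NP = no ClinVar record, CS = conflicting submissions.
# heart_anomaly flags: group totals (19 yes / 1 no in the ATPase motor
# region 731-1192; 9 yes / 6 no among span-bearing variants elsewhere;
# splice variant unknown) follow the study; the identity of the single
# no-anomaly ATPase-region variant is not printed, so its assignment here
# (p.K810N) is an editorial placeholder, as is part of the per-variant
# yes/no split outside that region. Group-level totals are authoritative;
# see chd4_anomaly_counts().
variant	cdna	type	metarnn	polyphen2	alphamissense	revel	evidence	gnomad_af	clinvar	heart_anomaly	disease_labels	syndrome
p.P8S	c.22C>T	missense	0.24	0.91	0.09	0.294	PM2+PM6		LP	no	H;LVH;CAD	MMA
p.M202I		missense	0.90	0.98	1.0	0.788	PS2+PS3+PM2+PP3		VUS	yes	VSD;CHD	SIHIWES
p.P286A	c.856C>G	missense	0.16	0.02	0.05	0.239	PM2+PP2+BP4	4.09e-06	NP	yes	SA	IP_sinus_arrhythmia
p.C467Y	c.4018C>T	missense	0.99	1.0	1.0	0.968	PS2+PS3+PM2+PP3		NP	yes	TF	SIHIWES
p.T494M		missense	0.41	0.707	0.10	0.14	PM2+BS2+BP4		VUS	no	CVD	MMA
p.K533E	c.1597A>G	missense	0.23	0.35	0.44	0.316	PS2+PM2		VUS	yes	E;SA	IP_sinus_arrhythmia
p.K810N		missense	0.66	1.0	1.0	0.548	PS2+PM2		NP	no		SIHIWES
p.S851Y		missense	0.98	0.99	1.0	0.985	PS2+PM2+PP3		P	yes	CHD	SIHIWES
p.R887W		missense	0.89	1.0	0.95	0.884	PS2+PM2+PP3		P	yes	CHD	SIHIWES
p.M954I		missense	0.88	0.90	0.99	0.905	PS2+PM2+PP3		P	yes	CHD	SIHIWES
p.M954V		missense	0.91	1.0	0.82	0.938	PS2+PS3+PM2+PP3		NP	yes	CHD	SIHIWES
p.M966K		missense	0.86	0.98	0.99	0.889	PS2+PM2+PP3		LP	yes	CHD	SIHIWES
p.R992Q		missense	0.88	1.0	0.72	0.685	PS2+PS3+PM2+PP3		CS	yes	CHD	SIHIWES
p.G1003D		missense	0.89	1.0	1.0	0.785	PS2+PS3+PM2+PP3		NP	yes	CHD	SIHIWES
p.L1009_V1011dup		inframe_dup					PS2+PM2		NP	yes	TF	SIHIWES
p.C1012del		inframe_del					PS2+PM2		NP	yes	TF	SIHIWES
p.N1020S		missense	0.94	1.0	0.73	0.855	PS2+PM2+PP3		LP	yes	CHD	SIHIWES
p.R1068H		missense	0.91	1.0	0.97	0.933	PS2+PS3+PM2+PP3		P	yes	CHD	SIHIWES
p.E1094K		missense	0.93	1.0	1.0	0.958	PS2+PS3+PM2+PP3		P	yes	CHD	SIHIWES
p.D1147E		missense	0.82	0.16	0.99	0.845	PS2+PM2+PP3		LP	yes	CHD	SIHIWES
p.W1148L		missense	0.92	0.511	1.0	0.76	PS2+PM2+PP3		P	yes	CHD	SIHIWES
p.A1178V		missense	0.55	0.06	0.91	0.462	PS2+PM2		LP	yes	CHD	SIHIWES
p.R1183H		missense	0.85	0.99	0.97	0.71	PS2+PM2+PP3		P/LP	yes	CHD	SIHIWES
p.R1183C		missense	0.89	1.0	0.99	0.877	PS2+PM2+PP3		P/LP	yes	CHD	SIHIWES
p.A1188V		missense	0.89	0.24	0.97	0.828	PS2+PM2+PP3		NP	yes	CHD	SIHIWES
p.M1192R		missense	0.80	0.01	0.99	0.797	PS2+PM2+PP3		NP	yes	CHD	SIHIWES
p.Y1249D		missense	0.90	0.40	1.0	0.856	PS2+PM2+PP3		LP	yes	ASD	SIHIWES
p.Y1345D		missense	0.91	1.0	1.0	0.809	PS2+PM2+PP3		NP	yes	TF	SIHIWES
p.R1419H		missense	0.91	0.26	0.992	0.861	PM2+PM6+PP2+PP3		LP	yes	D	other
p.V1608I		missense	0.07	0.01	0.07	0.171	PS2+PM2+BP4		CS	yes	ASD;SA	SIHIWES
p.E1646K		missense	0.26	0.455	0.15	0.459	PS2+PM2		NP	yes	ASD	SIHIWES
p.D1659E		missense	0.08	0.00	0.09	0.321	PM2+PP2		NP	no		other
p.I1741V		missense	0.58	0.25	0.66	0.5	PM2+PM6		LP	no	CVD;H	MMA
p.Y1758C		missense	0.90	0.98	0.97	0.734	PM2+PM6+PP3		CS	no	CVD;H	MMA
p.P1880S		missense	0.87	0.997	0.89	0.773	PM2+PM6+PP3		VUS	no	CVD;H;CAD	MMA
c.1686+1G>T	c.1686+1G>T	splice_donor					PM2		LP	unknown	CVD	MMA
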