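dataset	MaPSOGS	GeometricPSO	PSO	RMA	RPSW	EPSO	HybridBPSO-BBHA	PSOC4.5
AMLGSE2191	10	32	98	12	46	28	37	34
Colon	3	19	81	2	37	23	16	12
DLBCL	4	21	88	4	28	16	12	8
Leukaemia	6	18	85	5	24	21	28	24
Prostate	4	18	99	5	16	14	10	11
MLL	3	9	94	4	18	19	8	12
SRBCT	6	12	78	6	16	31	18	10
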