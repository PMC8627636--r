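dataset	MaPSOGS	GeometricPSO	PSO	RMA	RPSW	EPSO	HybridBPSO-BBHA	PSOC4.5
AMLGSE2191	100	89.01	82.29	96.29	90.48	91.63	94.26	96.88
Colon	99.52	89.93	86.63	100	91.38	91.01	92.25	95.27
DLBCL	98.84	86.08	83.54	95.15	94.24	91.75	92.06	92.65
Leukaemia	98.71	86.13	82.39	96.81	91.90	90.96	89.92	93.46
Prostate	98.38	85.96	84.55	97.41	90.51	89.14	87.92	91.81
MLL	96.38	81.26	81.67	91.23	86.53	85.98	86.75	91.63
SRBCT	98.91	84.56	83.28	95.37	91.50	90.11	91.70	93.03
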