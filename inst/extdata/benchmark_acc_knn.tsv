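dataset	MaPSOGS	GeometricPSO	PSO	RMA	RPSW	EPSO	HybridBPSO-BBHA	PSOC4.5
AMLGSE2191	95.36	87.08	81.16	95.11	90.79	91.22	91.05	93.39
Colon	96.18	86.76	84.88	94.10	90.55	88.21	90.36	91.45
DLBCL	93.89	86.96	82.83	91.49	91.18	89.64	88.07	90.39
Leukaemia	93.81	84.14	82.66	91.95	88.71	87.19	89.06	91.88
Prostate	94.25	80.83	82.69	93.77	90.26	85.55	86.37	90.04
MLL	93.74	81.49	80.90	91.55	83.72	88.78	86.44	90.61
SRBCT	94.90	81.96	81.13	92.53	90.11	90.01	88.83	91.39
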