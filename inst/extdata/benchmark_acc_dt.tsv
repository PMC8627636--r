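dataset	MaPSOGS	GeometricPSO	PSO	RMA	RPSW	EPSO	HybridBPSO-BBHA	PSOC4.5
AMLGSE2191	97.08	86.65	80.90	95.11	91.18	90.01	91.63	94.05
Colon	96.52	87.05	84.09	94.89	91.55	89.14	90.95	92.64
DLBCL	94.57	85.62	81.33	92.63	91.07	90.22	89.96	90.91
Leukaemia	95.42	83.39	82.12	92.89	89.69	88.43	88.53	91.57
Prostate	96.71	81.93	83.05	95.09	90.28	86.14	87.19	91.18
MLL	93.44	80.98	79.24	90.93	85.87	89.88	85.28	90.22
SRBCT	95.85	81.66	80.88	92.16	90.02	90.75	89.97	91.76
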