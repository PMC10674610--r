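label	quantity	est	lo	hi	scale
carbohydrate	total_or	0.54	0.31	0.92	or
MDD	beta1	-0.512	-0.731	-0.294	beta
MDD	or2	1.33	1.21	1.46	or
depressive_symptoms	beta1	-0.145	-0.235	-0.056	beta
depressive_symptoms	or2	2.03	1.60	2.57	or
neuroticism	beta1	-0.171	-0.270	-0.073	beta
neuroticism	or2	1.50	1.29	1.75	or
WHR	beta1	-0.357	-0.562	-0.152	beta
WHR	or2	1.84	1.55	2.18	or
HC	beta1	-0.468	-0.739	-0.197	beta
HC	or2	1.39	1.24	1.56	or
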