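# Synapse catalogue: conductance-based exponential synapses, one row per connection.
# g0 nS, tau_syn ms, E_rev mV, delay ms. plastic=1 rows carry Tsodyks-Markram
# facilitation/depression parameters (U utilisation, tau_rec ms, tau_fac ms;
# tau_fac=0 means no facilitation: utilisation resets to U at every spike).
# note: provenance / derivation of the value.
name	receptor	g0	tau_syn	E_rev	delay	plastic	U	tau_rec	tau_fac	note
MSN_D1-MSN_D1	GABA	0.15	8	-74	1.7	0	NA	NA	NA	weak collateral, paired-recording constrained
MSN_D1-MSN_D2	GABA	0.375	8	-74	1.7	0	NA	NA	NA	collateral
MSN_D2-MSN_D1	GABA	0.45	8	-74	1.7	0	NA	NA	NA	collateral
MSN_D2-MSN_D2	GABA	0.35	8	-74	1.7	0	NA	NA	NA	collateral
FSN-MSN_D1	GABA	6	11	-74	1.7	1	0.29	902	53	feed-forward, depressing
FSN-MSN_D2	GABA	6	11	-74	1.7	1	0.29	902	53	feed-forward, depressing
FSN-FSN	GABA	1	6	-74	1.7	1	0.29	902	53	several times weaker than FSN-MSN
GPe_TA-MSN_D1	GABA	0.04	87	-74	7	0	NA	NA	NA	slow arkypallidal synapse
GPe_TA-MSN_D2	GABA	0.08	76	-74	7	0	NA	NA	NA	twice TA-MSN D1
GPe_TA-FSN	GABA	0.51	66	-74	7	1	0.29	902	53	depressing, FD params as FSN-MSN
GPe_TI-FSN	GABA	2	17	-74	7	1	0.29	902	53	fast prototypical synapse, depressing
MSN_D2-GPe_TI	GABA	2	6	-65	7	0	NA	NA	NA	indirect-pathway projection
GPe_TA-GPe_TA	GABA	0.33	5	-65	1	0	NA	NA	NA	25% of GPe-GPe TI weight
GPe_TA-GPe_TI	GABA	1.3	5	-65	1	0	NA	NA	NA	pallidal collateral
GPe_TI-GPe_TA	GABA	0.33	5	-65	1	0	NA	NA	NA	25% of GPe-GPe TI weight
GPe_TI-GPe_TI	GABA	1.3	5	-65	1	0	NA	NA	NA	pallidal collateral
STN-GPe_TI	AMPA	0.35	12	0	2	0	NA	NA	NA	subthalamo-pallidal
STN-GPe_TA	AMPA	0.11	12	0	2	0	NA	NA	NA	30% of STN-GPe TI
GPe_TI-STN	GABA	0.08	8	-84	1	0	NA	NA	NA	pallido-subthalamic
GPe_TI-SNr	GABA	76	2.1	-72	3	1	0.196	969	0	strong depressing pallido-nigral
MSN_D1-SNr	GABA	2	5.2	-80	7	1	0.0192	623	559	facilitating direct-pathway synapse
MSN_D2-SNr	GABA	2	5.2	-80	7	1	0.24	11	73	catalogue entry; not wired in the standard network
STN-SNr	AMPA	0.91	12	0	4.5	1	0.35	800	0	depressing
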