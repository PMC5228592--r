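# Dopamine-occupancy modulation catalogue: p <- p * (1 + beta * (alpha - 0.8)).
# kind: syn_g0 (synaptic conductance), drive_g0 (extrinsic-drive conductance,
# field names the receptor), fan_in (connection in-degree, rounded half-up,
# floor 0), neuron (neuron parameter; field names it).
# constraint: the experimental ratio/shift each beta was derived from
# (ratio R = value at occupancy 0 over value at occupancy 1; shift in mV).
name	kind	target	field	beta	constraint
FSN-FSN	syn_g0	FSN-FSN	g0	-1.27	ratio 2.7
GPe_TA-FSN	syn_g0	GPe_TA-FSN	g0	-0.53	ratio 1.6
GPe_TI-FSN	syn_g0	GPe_TI-FSN	g0	-0.53	ratio 1.6
GPe_TA-GPe_TA	syn_g0	GPe_TA-GPe_TA	g0	-0.83	ratio 2
GPe_TA-GPe_TI	syn_g0	GPe_TA-GPe_TI	g0	-0.83	ratio 2
GPe_TI-GPe_TA	syn_g0	GPe_TI-GPe_TA	g0	-0.83	ratio 2
GPe_TI-GPe_TI	syn_g0	GPe_TI-GPe_TI	g0	-0.83	ratio 2
MSN_D2-GPe_TI	syn_g0	MSN_D2-GPe_TI	g0	-0.83	ratio 2
STN-GPe_TI	syn_g0	STN-GPe_TI	g0	-0.45	ratio 1.5
STN-GPe_TA	syn_g0	STN-GPe_TA	g0	-0.45	ratio 1.5
CTX-MSN_D1-NMDA	drive_g0	CTX-MSN_D1	nmda_g0	1.04	ratio 0.14
CTX-MSN_D2-AMPA	drive_g0	CTX-MSN_D2	ampa_g0	-0.26	ratio 1.27
FSN-MSN_D2-fanin	fan_in	FSN-MSN_D2	fan_in	-0.90	2x at occupancy 0 vs basal 0.8 (catalogue value kept)
MSN_D1-MSN_D1	syn_g0	MSN_D1-MSN_D1	g0	0.88	ratio 0.25
MSN_D1-MSN_D2	syn_g0	MSN_D1-MSN_D2	g0	0.88	ratio 0.25
MSN_D2-MSN_D1	syn_g0	MSN_D2-MSN_D1	g0	0.88	ratio 0.25
MSN_D2-MSN_D2	syn_g0	MSN_D2-MSN_D2	g0	0.88	ratio 0.25
MSN_D1-MSN_D1-fanin	fan_in	MSN_D1-MSN_D1	fan_in	0.88	ratio 0.25
MSN_D1-MSN_D2-fanin	fan_in	MSN_D1-MSN_D2	fan_in	0.88	ratio 0.25
MSN_D2-MSN_D1-fanin	fan_in	MSN_D2-MSN_D1	fan_in	0.88	ratio 0.25
MSN_D2-MSN_D2-fanin	fan_in	MSN_D2-MSN_D2	fan_in	0.88	ratio 0.25
GPe_TA-MSN_D1	syn_g0	GPe_TA-MSN_D1	g0	-1.22	ratio 2.6
GPe_TA-MSN_D2	syn_g0	GPe_TA-MSN_D2	g0	-1.15	ratio 2.5 (catalogue label misprints target as MSN D1)
MSN_D1-SNr	syn_g0	MSN_D1-SNr	g0	0.56	ratio 0.5 (standard 1+beta*phi form)
CTX-STN-AMPA	drive_g0	CTX-STN	ampa_g0	-0.45	catalogue value; stated 2.5x ratio inconsistent with it
CTX-STN-NMDA	drive_g0	CTX-STN	nmda_g0	-0.45	same scaling as AMPA
GPe_TI-STN	syn_g0	GPe_TI-STN	g0	-0.24	ratio 1.25
MSN_D1-v_r	neuron	MSN_D1	v_r	0.0296	D1 hyperpolarising KIR effect
MSN_D1-d	neuron	MSN_D1	d	-0.450	D1 enhanced response to depolarising input
FSN-v_r	neuron	FSN	v_r	-0.078	5 mV lower at occupancy 0 than at 1
GPe_TA-E_L	neuron	GPe_TA	E_L	-0.181	10 mV lower at occupancy 0 than at 1
GPe_TI-E_L	neuron	GPe_TI	E_L	-0.181	10 mV lower at occupancy 0 than at 1
SNr-E_L	neuron	SNr	E_L	-0.0896	5 mV lower at occupancy 0 than at 1
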