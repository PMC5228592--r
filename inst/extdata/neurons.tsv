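# Point-neuron parameter catalogue, one row per (population, parameter).
# family: qif  = quadratic integrate-and-fire with adaptation (striatal neurons)
#         adex = adaptive exponential integrate-and-fire (pallidal/nigral/subthalamic)
# Units: C pF; voltages mV; conductances nS; currents pA; tau ms; qif `a` in 1/ms
# (catalogue sources print it in s for these canonical parameter sets); qif `b`,`k`
# dimensionless in this unit system; adex `a_sub` nS.
# note: experimental constraint or derivation carried with the value.
population	family	param	value	note
MSN_D1	qif	C	15.2	membrane capacitance
MSN_D1	qif	k	1	steady-state I-V coefficient
MSN_D1	qif	v_r	-78.2	resting potential
MSN_D1	qif	v_th	-29.7	threshold potential
MSN_D1	qif	v_peak	40	spike cutoff
MSN_D1	qif	c	-60	spike reset
MSN_D1	qif	a	0.01	recovery rate constant
MSN_D1	qif	b	-20	recovery voltage dependence
MSN_D1	qif	d	66.9	spike-triggered recovery increment
MSN_D2	qif	C	15.2	membrane capacitance
MSN_D2	qif	k	1	steady-state I-V coefficient; D2 alpha=0.032 modulation stored separately, off by default
MSN_D2	qif	v_r	-80	resting potential (D2 slightly more excitable via smaller surface)
MSN_D2	qif	v_th	-29.7	threshold potential
MSN_D2	qif	v_peak	40	spike cutoff
MSN_D2	qif	c	-60	spike reset
MSN_D2	qif	a	0.01	recovery rate constant
MSN_D2	qif	b	-20	recovery voltage dependence
MSN_D2	qif	d	91	spike-triggered recovery increment
FSN	qif	C	80	membrane capacitance
FSN	qif	k	1	steady-state I-V coefficient
FSN	qif	v_r	-64.4	resting potential
FSN	qif	v_th	-50	threshold potential
FSN	qif	v_peak	25	spike cutoff
FSN	qif	c	-60	spike reset
FSN	qif	a	0.2	recovery rate constant
FSN	qif	b	0.025	recovery voltage dependence (cubic branch)
FSN	qif	d	0	spike-triggered recovery increment
FSN	qif	v_b	-55	recovery kink voltage; cubic recovery below, pure decay above (type-2 onset)
GPe_TI	adex	C	40	membrane capacitance, prototypical cells
GPe_TI	adex	g_L	1	leak conductance
GPe_TI	adex	E_L	-55.1	leak reversal; depolarised pacemaker
GPe_TI	adex	V_T	-54.7	threshold potential
GPe_TI	adex	Delta_T	1.7	spike slope factor
GPe_TI	adex	a_sub	2.5	subthreshold adaptation
GPe_TI	adex	tau_w	20	adaptation time constant
GPe_TI	adex	b_spike	70	spike-triggered adaptation
GPe_TI	adex	V_r	-60	spike reset
GPe_TI	adex	t_f	15	spike cutoff
GPe_TI	adex	I_e	12	bias giving 18 Hz in vitro rate without synaptic input
GPe_TA	adex	C	60	150% of TI (flatter f-I curve, 60% of TI slope)
GPe_TA	adex	g_L	1	leak conductance
GPe_TA	adex	E_L	-55.1	leak reversal
GPe_TA	adex	V_T	-54.7	threshold potential
GPe_TA	adex	Delta_T	2.55	150% of TI
GPe_TA	adex	a_sub	2.5	subthreshold adaptation
GPe_TA	adex	tau_w	20	adaptation time constant
GPe_TA	adex	b_spike	105	150% of TI
GPe_TA	adex	V_r	-60	spike reset
GPe_TA	adex	t_f	15	spike cutoff
GPe_TA	adex	I_e	1	bias giving 8 Hz in vitro rate without synaptic input
SNr	adex	C	80	membrane capacitance
SNr	adex	g_L	3	leak conductance
SNr	adex	E_L	-55.8	leak reversal
SNr	adex	V_T	-55.2	threshold potential
SNr	adex	Delta_T	1.8	spike slope factor
SNr	adex	a_sub	3	subthreshold adaptation
SNr	adex	tau_w	20	adaptation time constant
SNr	adex	b_spike	200	spike-triggered adaptation
SNr	adex	V_r	-65	spike reset
SNr	adex	t_f	20	spike cutoff
SNr	adex	I_e	15	bias giving in vitro tonic rate without synaptic input
STN	adex	C	60	membrane capacitance
STN	adex	g_L	10	leak conductance
STN	adex	E_L	-80.2	leak reversal
STN	adex	V_T	-64	threshold potential
STN	adex	Delta_T	16.2	spike slope factor (steep f-I curve)
STN	adex	a_sub	0.3	subthreshold adaptation, active only below the -70 mV gate
STN	adex	tau_w	333	adaptation time constant
STN	adex	b_spike	0.05	spike-triggered adaptation
STN	adex	V_r	-70	spike reset (rebound variant adds max(w-15,20) when w<0)
STN	adex	t_f	15	spike cutoff
STN	adex	I_e	5	bias giving in vitro tonic rate without synaptic input
STN	adex	adaptation_gate	-70	voltage below which a_sub applies
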