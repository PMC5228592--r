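# Extrinsic Poisson drives (cortex / thalamus), one row per target population.
# rate_slow / rate_act Hz: mean rate during cortical slow-wave vs activation.
# amp_slow / amp_act: square-wave modulation amplitude a (rate alternates
# v(1+a) / v(1-a) every half cycle; 1 Hz slow-wave modulation in both
# conditions, 20 Hz beta modulation during activation only in the
# dopamine-depleted condition). NMDA columns NA = AMPA-only drive.
# Conductances nS, tau ms, E_rev mV.
name	target	rate_slow	rate_act	amp_slow	amp_act	ampa_g0	ampa_tau	nmda_g0	nmda_tau	E_rev
CTX-MSN_D1	MSN_D1	448	546	0.11	0.11	0.5	12	0.11	160	0
CTX-MSN_D2	MSN_D2	592	722	0.11	0.11	0.5	12	0.019	160	0
CTX-FSN	FSN	646	787	0.11	0.11	0.5	12	NA	NA	0
CTX-STN	STN	170	250	0.11	0.35	0.25	4	0.00625	160	0
EXT-GPe_TA	GPe_TA	100	200	0	0	0.5	5	NA	NA	0
EXT-GPe_TI	GPe_TI	720	1530	0	0	0.5	5	NA	NA	0
EXT-SNr	SNr	1800	1800	0	0	0.5	5	NA	NA	0
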