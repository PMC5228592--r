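# Fan-in connectivity, one row per connection: each postsynaptic neuron receives
# exactly fan_in distinct presynaptic partners. window = size of the index-ring
# spatial neighbourhood in the presynaptic population (NA = whole population).
# pre_fraction: fraction of the presynaptic population eligible to project
# (GPe TI -> FSN comes from the 10% of TI cells that project back to striatum).
# synapse: row name in synapses.tsv.
name	pre	post	fan_in	window	pre_fraction	synapse
MSN_D1-MSN_D1	MSN_D1	MSN_D1	364	2800	1	MSN_D1-MSN_D1
MSN_D1-MSN_D2	MSN_D1	MSN_D2	84	2800	1	MSN_D1-MSN_D2
MSN_D2-MSN_D1	MSN_D2	MSN_D1	392	2800	1	MSN_D2-MSN_D1
MSN_D2-MSN_D2	MSN_D2	MSN_D2	504	2800	1	MSN_D2-MSN_D2
FSN-MSN_D1	FSN	MSN_D1	16	540	1	FSN-MSN_D1
FSN-MSN_D2	FSN	MSN_D2	11	540	1	FSN-MSN_D2
FSN-FSN	FSN	FSN	10	NA	1	FSN-FSN
GPe_TA-MSN_D1	GPe_TA	MSN_D1	10	NA	1	GPe_TA-MSN_D1
GPe_TA-MSN_D2	GPe_TA	MSN_D2	10	NA	1	GPe_TA-MSN_D2
GPe_TA-FSN	GPe_TA	FSN	10	NA	1	GPe_TA-FSN
GPe_TI-FSN	GPe_TI	FSN	10	NA	0.1	GPe_TI-FSN
MSN_D2-GPe_TI	MSN_D2	GPe_TI	500	NA	1	MSN_D2-GPe_TI
GPe_TA-GPe_TA	GPe_TA	GPe_TA	5	NA	1	GPe_TA-GPe_TA
GPe_TA-GPe_TI	GPe_TA	GPe_TI	5	NA	1	GPe_TA-GPe_TI
GPe_TI-GPe_TA	GPe_TI	GPe_TA	25	NA	1	GPe_TI-GPe_TA
GPe_TI-GPe_TI	GPe_TI	GPe_TI	25	NA	1	GPe_TI-GPe_TI
STN-GPe_TI	STN	GPe_TI	30	NA	1	STN-GPe_TI
STN-GPe_TA	STN	GPe_TA	30	NA	1	STN-GPe_TA
GPe_TI-STN	GPe_TI	STN	30	NA	1	GPe_TI-STN
GPe_TI-SNr	GPe_TI	SNr	32	NA	1	GPe_TI-SNr
MSN_D1-SNr	MSN_D1	SNr	500	NA	1	MSN_D1-SNr
STN-SNr	STN	SNr	30	NA	1	STN-SNr
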