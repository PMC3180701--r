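reaction_id	compound	mg_per_kg	min	max	provenance	group
mue	lignin-growth	NA	2.70e-2	2.70e-2	fixed-value	growth
RXN1F-775	cpd1f-766	28.9	6.43e-2	6.43e-2	fixed-value	anthocyanins
RXN-8204	cpd-7866	1.4	2.35e-3	2.35e-3	fixed-value	anthocyanins
RXN1F-461	cpd1f-453	97.7	1.64e-1	1.64e-1	fixed-value	flavonols
RXN1F-462	cpd1f-437	37.3	8.03e-2	8.03e-2	fixed-value	flavonols
RXN-9724	CPD-10413	NA	3.58e-2	3.58e-2	fixed-value	flavan-3-ols
RXN-9725	CPD-7630	NA	3.58e-2	3.58e-2	fixed-value	flavan-3-ols
RXN-1481	CPD-1962	NA	3.58e-2	3.58e-2	fixed-value	flavan-3-ols
RXN-1484	CPD-1961	NA	3.58e-2	3.58e-2	fixed-value	flavan-3-ols
luteolin	5734-TETRAHYDROXYFLAVONE	NA	0	5.02e+1	range	other
apigenin	cpd-431	NA	0	1.44e+1	range	other
methylsalicylate	methylsalicylate	NA	0	1.15e-2	range	other
methylbenzoate	methylbenzoate	NA	0	2.27e+1	range	other
4-coumarate	4-coumarate	NA	0	1.84e+0	range	other
caffeate	caffeate	NA	0	3.10e-1	range	other
ferulate	ferulate	NA	0	4.50e-1	range	other
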