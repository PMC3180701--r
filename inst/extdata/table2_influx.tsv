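reaction_id	rate
CAFFEATE-O-METHYLTRANSFERASE-RXN	8.40e+1
CONIFERIN-BETA-GLUCOSIDASE-RXN	4.51e+1
BENZYL-ALC-DEHYDROGENASE-RXN	2.98e+1
RXN-5482	1.44e+0
CINNAMYL-ALCOHOL-DEHYDROGENASE-RXN	9.26e+1
TYROSINE-DECARBOXYLASE-RXN	1.01e+2
PHEAMINOTRANS-RXN	9.26e+1
MANDELONITRILE-LYASE-RXN	2.98e+1
UDP-GLUCOSE-4,6-DEHYDRATASE-RXN	2.41e+0
DAHPSYN-RXN	9.07e+1
TYROSINE-AMINOTRANSFERASE-RXN	6.17e+1
PHENYLPYRUVATE-DECARBOXYLASE-RXN	5.00e+1
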