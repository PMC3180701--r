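class	kind	compound
anthocyanins	flavonoid	cpd1f-766
anthocyanins	flavonoid	cpd-7866
flavanols	flavonoid	NA
flavanones	flavonoid	cpd-3041
flavones	flavonoid	5734-TETRAHYDROXYFLAVONE
flavones	flavonoid	cpd-431
flavonols1	flavonoid	cpd1f-453
flavonols2	flavonoid	cpd1f-437
leucoanthocyanidins	flavonoid	NA
proanthocyanidins	flavonoid	CPD-10413
proanthocyanidins	flavonoid	CPD-7630
proanthocyanidins	flavonoid	CPD-1962
proanthocyanidins	flavonoid	CPD-1961
lignin	non-flavonoid	NA
benzenoids	non-flavonoid	methylbenzoate
benzenoids	non-flavonoid	methylsalicylate
amides	non-flavonoid	NA
coumarins	non-flavonoid	NA
others	other	NA
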