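# topology: linear
psbA	+	gene
trnV-rbcL	-	gene
trnT-ndhC	-	gene
trnC-rps4	-	gene
trnR-rpoB	-	gene
trnK-trnG	-	gene
psaI	+	gene
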