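# topology: linear
psbA	+	gene
trnK-trnG	+	gene
trnR-rpoB	+	gene
trnC-rps4	+	gene
trnT-ndhC	+	gene
trnV-rbcL	+	gene
psaI	+	gene
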