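# MDS-PSP combination table: phenotype, diagnostic certainty, and the
# qualifying feature combination in disjunctive normal form.
# Conjuncts are separated by '|', literals within a conjunct by '+'.
phenotype	certainty	formula
PSP-RS	probable	O1+P1 | O1+P2 | O2+P1 | O2+P2
PSP-RS	possible	O2+P3
PSP-RS	suggestive of	O3+P2 | O3+P3
PSP-P	probable	O1+A2 | O1+A3 | O2+A2 | O2+A3
PSP-P	suggestive of	A2+O3 | A2+P1 | A2+P2 | A2+C1 | A2+C2 | A2+CC1 | A2+CC2 | A2+CC3 | A2+CC4 | A3+O3 | A3+P1 | A3+P2 | A3+C1 | A3+C2 | A3+CC1 | A3+CC2 | A3+CC3 | A3+CC4
PSP-PGF	probable	O1+A1 | O2+A1
PSP-PGF	possible	A1
PSP-F	probable	C2+O1 | C2+O2
PSP-F	suggestive of	C2+O3 | C2+P3
PSP-OM	possible	O1
PSP-OM	suggestive of	O2 | O3
PSP-SL	possible	O1+C1 | O2+C1
PSP-SL	suggestive of	C1
PSP-CBS	possible	O1+C3 | O2+C3
PSP-CBS	suggestive of	C3
PSP-PI	suggestive of	P1 | P2
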