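# Probable 4R-tauopathy membership by (phenotype, certainty).
# Default imported from the MDS criteria publication (Hoeglinger et al. 2017,
# Mov Disord 32:853-864): probable PSP of any phenotype, or possible PSP with
# predominant corticobasal syndrome (joint PSP/CBD trial category), qualify.
# Override with psp_tau_map(path) pointing at a file of the same shape.
phenotype	certainty	tau_4r
PSP-RS	probable	yes
PSP-RS	possible	no
PSP-RS	suggestive of	no
PSP-P	probable	yes
PSP-P	possible	no
PSP-P	suggestive of	no
PSP-PGF	probable	yes
PSP-PGF	possible	no
PSP-PGF	suggestive of	no
PSP-F	probable	yes
PSP-F	possible	no
PSP-F	suggestive of	no
PSP-OM	probable	yes
PSP-OM	possible	no
PSP-OM	suggestive of	no
PSP-SL	probable	yes
PSP-SL	possible	no
PSP-SL	suggestive of	no
PSP-CBS	probable	yes
PSP-CBS	possible	yes
PSP-CBS	suggestive of	no
PSP-PI	probable	yes
PSP-PI	possible	no
PSP-PI	suggestive of	no
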