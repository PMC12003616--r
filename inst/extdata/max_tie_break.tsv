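# Residual tie-break order among phenotypes once certainty, temporal order
# and PSP-RS precedence have all failed to single out one allocation.
# PSP-RS sits at the apex; the variant order below it is a fixed,
# documented convention (the criteria print no order among variants).
phenotype
PSP-RS
PSP-PGF
PSP-P
PSP-F
PSP-SL
PSP-CBS
PSP-OM
PSP-PI
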