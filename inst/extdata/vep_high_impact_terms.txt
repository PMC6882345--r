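# Ensembl VEP consequence terms with impact class HIGH (Ensembl release 110).
# One term per line; matching is case-insensitive. Override via the
# high.impact.terms option in the configuration file.
transcript_ablation
splice_acceptor_variant
splice_donor_variant
stop_gained
frameshift_variant
stop_lost
start_lost
transcript_amplification
feature_elongation
feature_truncation
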