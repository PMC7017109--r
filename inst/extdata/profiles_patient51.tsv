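# Worked-example profile: hormone-positive breast carcinoma.
# The Her2-negative finding is retained for reporting; it is not scoreable.
patient_id	gene	alteration_class	pathogenic	detail
P51	ER	expression_positive	TRUE	estrogen receptor positive
P51	PR	expression_positive	TRUE	progesterone receptor positive
P51	ERBB2	expression_negative	FALSE	Her2 negative
P51	PTEN	copy_loss	TRUE	gene-copy loss
P51	CCND1	amplification	TRUE	gene-copy amplification
P51	FGFR1	amplification	TRUE	gene-copy amplification
P51	PRKDC	amplification	TRUE	gene-copy amplification
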