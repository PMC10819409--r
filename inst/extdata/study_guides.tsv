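# Guide RNAs used in the study: protospacer, observed PAM, degenerate PAM pattern and PAM side per Cas system
guide_id	gene	protospacer	pam_observed	pam_pattern	pam_side	cas_label
kcnq2_c875_877	KCNQ2	ACCCCCAGACCTGGAACGGC	AGG	NGG	three_prime	Cas9
kcnq2_c766	KCNQ2	TCTCATCCTGGCCTCGTTCC	TGG	NGG	three_prime	Cas9
kcnq2_c821	KCNQ2	GCTGACCACCATTGGCTACG	GGG	NGG	three_prime	Cas9
ash1l_c773	ASH1L	ATCAGGAAAGCAGTGTTGGC	TTTG	TTTV	five_prime	Cas12a
ash1l_c4902_4903	ASH1L	GTCCTGTGCAGAAGAGTCCA	GGG	NGG	three_prime	Cas9
ash1l_c1958	ASH1L	CAAGGGAAGAGCTTATTCTT	TTTC	TTTV	five_prime	Cas12a
gnaq_c548	GNAQ	CTAAGCACATCTTGTTGCGT	AGG	NGG	three_prime	Cas9
hprt1_cas9	HPRT1	GATGATCTCTCAACTTTAAC	TGG	NGG	three_prime	Cas9
hprt1_cas12a	HPRT1	TGTAGGACTGAACGTCTTGCTCG	TTTC	TTTV	five_prime	Cas12a
nontarget_cas9	nontarget	GCACTACCAGAGCTAACTCA	NA	NGG	three_prime	Cas9
nontarget_cas12a	nontarget	CGTTAATCGCGTATAATACGG	NA	TTTV	five_prime	Cas12a
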