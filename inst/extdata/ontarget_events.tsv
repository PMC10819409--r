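# Unintended on-target modifications near the edited loci (hg19), one row per lesion.
# Lesions sharing (clone_id, event_id) are physically linked and count as a single event.
clone_id	event_id	contig	start	end	gene	lesion_type	description
HNDS0078-01 #D CC8	CC8_e1	chr20	62073873	62073875	KCNQ2	MNV	3-bp substitution AGT>CTG (p.T234L) at the repair-template edge
HNDS0072-01 #C CC80	CC80_e1	chr20	62071037	62071037	KCNQ2	insertion	71-bp frameshift insertion
HNDS0072-01 #C CC80	CC80_e1	chr20	62068445	62070301	KCNQ2	deletion	1857-bp mono-allelic deletion linked to the insertion
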