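# DNA-detectable sequence-ontology terms (default whitelist; override with
# any character vector of SO accessions)
so_id	term
SO:0001583	missense_variant
SO:0001587	stop_gained
SO:0001578	stop_lost
SO:0002012	start_lost
SO:0001589	frameshift_variant
SO:0001821	inframe_insertion
SO:0001822	inframe_deletion
SO:0001818	protein_altering_variant
SO:0001819	synonymous_variant
SO:0001574	splice_acceptor_variant
SO:0001575	splice_donor_variant
SO:0001630	splice_region_variant
SO:0001627	intron_variant
SO:0001623	5_prime_UTR_variant
SO:0001624	3_prime_UTR_variant
SO:0001619	non_coding_transcript_variant
SO:0001060	sequence_variant
SO:0000159	deletion
SO:0000667	insertion
SO:1000032	delins
SO:0001483	SNV
SO:0002007	MNV
SO:0001059	sequence_alteration
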