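part_id	name	category	is_cds
oriEx	example origin	origin of replication	FALSE
promEx	example promoter	promoter	FALSE
cdsEx	example CDS	CDS	TRUE
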