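plasmid_id	lab_id
pGb1	smith lab
pGb2	jones lab
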