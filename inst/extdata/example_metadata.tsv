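plasmid_id	lab_id
pEx1	smith lab
pEx2	smith lab
pEx3	jones lab
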