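attribute,source_value,radlex_id
body_part_examined,CHEST,RID-SYN-0001
body_part_examined,BRAIN,RID-SYN-0002
body_part_examined,ABDOMEN,RID-SYN-0003
modality,CT,RID-SYN-0101
modality,MR,RID-SYN-0102
modality,CR,RID-SYN-0103
modality,DX,RID-SYN-0104
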