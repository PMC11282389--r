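attribute,source_value,concept_id
modality,CT,91001001
modality,MR,91001002
modality,CR,91001003
modality,DX,91001004
body_part_examined,CHEST,91002001
body_part_examined,BRAIN,91002002
body_part_examined,HEAD,91002002
body_part_examined,ABDOMEN,91002003
laterality,L,91003001
laterality,R,91003002
laterality,B,91003003
patient_position,HFS,91004001
patient_position,FFS,91004002
patient_position,HFP,91004003
bb_non_bb,POSITIVE,45884084
bb_non_bb,NEGATIVE,45878583
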