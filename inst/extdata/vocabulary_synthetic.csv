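concept_id,concept_name,domain,vocabulary,standard_flag
91000001,Slice thickness,Imaging Attribute,ICDM-Synthetic,TRUE
91000002,Rows,Imaging Attribute,ICDM-Synthetic,TRUE
91000003,Columns,Imaging Attribute,ICDM-Synthetic,TRUE
91000004,Window center,Imaging Attribute,ICDM-Synthetic,TRUE
91000005,Window width,Imaging Attribute,ICDM-Synthetic,TRUE
91000006,Body part examined,Imaging Attribute,ICDM-Synthetic,TRUE
91000007,Laterality,Imaging Attribute,ICDM-Synthetic,TRUE
91000008,Patient position,Imaging Attribute,ICDM-Synthetic,TRUE
91000009,Series description,Imaging Attribute,ICDM-Synthetic,TRUE
91000010,Number of instances,Imaging Attribute,ICDM-Synthetic,TRUE
91000011,BB/non-BB,Imaging Attribute,ICDM-Synthetic,TRUE
91000012,Annotation system,Imaging Attribute,ICDM-Synthetic,TRUE
91000013,Annotation text,Imaging Attribute,ICDM-Synthetic,TRUE
91000014,Volume,Imaging Attribute,ICDM-Synthetic,TRUE
91000015,Long axis,Imaging Attribute,ICDM-Synthetic,TRUE
91000016,Surface area,Imaging Attribute,ICDM-Synthetic,TRUE
91001001,Computed tomography imaging procedure,Procedure,ICDM-Synthetic,TRUE
91001002,Magnetic resonance imaging procedure,Procedure,ICDM-Synthetic,TRUE
91001003,Computed radiography imaging procedure,Procedure,ICDM-Synthetic,TRUE
91001004,Digital radiography imaging procedure,Procedure,ICDM-Synthetic,TRUE
91002001,Chest imaging,Procedure,ICDM-Synthetic,TRUE
91002002,Brain imaging,Procedure,ICDM-Synthetic,TRUE
91002003,Abdomen imaging,Procedure,ICDM-Synthetic,TRUE
91003001,Left,Meas Value,ICDM-Synthetic,TRUE
91003002,Right,Meas Value,ICDM-Synthetic,TRUE
91003003,Bilateral,Meas Value,ICDM-Synthetic,TRUE
91004001,Head first supine,Meas Value,ICDM-Synthetic,TRUE
91004002,Feet first supine,Meas Value,ICDM-Synthetic,TRUE
91004003,Head first prone,Meas Value,ICDM-Synthetic,TRUE
91005001,Primary lung cancer,Condition,ICDM-Synthetic,TRUE
91005002,Essential hypertension,Condition,ICDM-Synthetic,TRUE
91006001,Osimertinib,Drug,ICDM-Synthetic,TRUE
45884084,Black-Blood positive,Meas Value,ICDM-Synthetic,TRUE
45878583,Black-Blood negative,Meas Value,ICDM-Synthetic,TRUE
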