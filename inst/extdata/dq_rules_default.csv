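rule_id,table,attribute,archetype,threshold_pct,lo_pct,hi_pct,max_outlier_pct,valid_values,antecedent,consequent,description
IS-01,imaging_study,number_of_series,count_consistency,95,,,,,,,NUMBER_OF_SERIES must equal the number of series rows in IMAGING_SERIES for the same study
IS-02,imaging_study,number_of_instances,sum_consistency,95,,,,,,,NUMBER_OF_INSTANCE must equal the aggregated instance count from the series rows
IS-03,imaging_study,,co_presence,95,,,,,number_of_series,number_of_instances,Presence of NUMBER_OF_SERIES necessitates presence of NUMBER_OF_INSTANCE
IS-04,imaging_study,number_of_series,nonmissing_numeric,99,,,,,,,NUMBER_OF_SERIES must exist and be numeric
IS-05,imaging_study,number_of_instances,nonmissing_numeric,99,,,,,,,NUMBER_OF_INSTANCE must exist and be numeric
IS-06,imaging_study,modality_source_value,nonempty_text,99,,,,,,,Modality source value must be nonempty
IS-07,imaging_study,manufacturer_source_value,nonempty_text,99,,,,,,,Manufacturer source value must be nonempty
IS-08,imaging_study,study_date,nonempty_text,99,,,,,,,Study date must be nonempty
IS-09,imaging_study,number_of_series,outlier_percentile,,1,99,5,,,,Series counts beyond the 1st and 99th percentiles should be reviewed
IS-10,imaging_study,number_of_instances,outlier_percentile,,1,99,5,,,,Instance counts beyond the 1st and 99th percentiles should be reviewed
SE-01,imaging_series,slice_thickness,nonmissing_numeric,99,,,,,,,VALUE_AS_NUMBER must exist and be numeric for slice thickness rows
SE-02,imaging_series,slice_thickness,outlier_percentile,,1,99,5,,,,Slice thickness values beyond the 1st and 99th percentiles should be reviewed
SE-03,imaging_series,rows,nonmissing_numeric,99,,,,,,,VALUE_AS_NUMBER must exist and be numeric for rows
SE-04,imaging_series,rows,outlier_percentile,,1,99,5,,,,Row counts beyond the 1st and 99th percentiles should be reviewed
SE-05,imaging_series,columns,nonmissing_numeric,99,,,,,,,VALUE_AS_NUMBER must exist and be numeric for columns
SE-06,imaging_series,columns,outlier_percentile,,1,99,5,,,,Column counts beyond the 1st and 99th percentiles should be reviewed
SE-07,imaging_series,window_center,nonmissing_numeric,99,,,,,,,VALUE_AS_NUMBER must exist and be numeric for window center
SE-08,imaging_series,window_center,outlier_percentile,,1,99,5,,,,Window center values beyond the 1st and 99th percentiles should be reviewed
SE-09,imaging_series,window_width,nonmissing_numeric,99,,,,,,,VALUE_AS_NUMBER must exist and be numeric for window width
SE-10,imaging_series,window_width,outlier_percentile,,1,99,5,,,,Window width values beyond the 1st and 99th percentiles should be reviewed
SE-11,imaging_series,number_of_instances,nonmissing_numeric,99,,,,,,,VALUE_AS_NUMBER must exist and be numeric for per-series instance counts
SE-12,imaging_series,number_of_instances,outlier_percentile,,1,99,5,,,,Per-series instance counts beyond the 1st and 99th percentiles should be reviewed
SE-13,imaging_series,bb_non_bb,value_set,100,,,,45884084;45878583,,,BB/non-BB values must be one of the two valid status concept ids
SE-14,imaging_series,body_part_examined,nonempty_text,100,,,,,,,Body part examined source value must be nonempty
SE-15,imaging_series,laterality,nonempty_text,100,,,,,,,Laterality source value must be nonempty
SE-16,imaging_series,patient_position,nonempty_text,100,,,,,,,Patient position source value must be nonempty
SE-17,imaging_series,series_description,nonempty_text,100,,,,,,,Series description source value must be nonempty
SE-18,imaging_series,laterality,value_set,100,,,,91003001;91003002;91003003,,,Laterality concepts must be left or right or bilateral
SE-19,imaging_series,patient_position,value_set,100,,,,91004001;91004002;91004003,,,Patient position concepts must be in the mapped position set
SE-20,imaging_series,body_part_examined,value_set,100,,,,91002001;91002002;91002003,,,Body part concepts must be in the mapped body part set
SE-21,imaging_series,,co_presence,95,,,,,rows,columns,Presence of a rows attribute necessitates a columns attribute
AN-01,imaging_annotation,long_axis,nonmissing_numeric,100,,,,,,,VALUE_AS_NUMBER must exist and be numeric for long axis rows
AN-02,imaging_annotation,long_axis,outlier_percentile,,1,99,5,,,,Long axis values beyond the 1st and 99th percentiles should be reviewed
AN-03,imaging_annotation,volume,nonmissing_numeric,100,,,,,,,VALUE_AS_NUMBER must exist and be numeric for volume rows
AN-04,imaging_annotation,annotation_text,nonempty_text,100,,,,,,,VALUE_SOURCE_VALUE must contain a nonempty text value
AN-05,imaging_annotation,surface,nonmissing_numeric,100,,,,,,,VALUE_AS_NUMBER must exist and be numeric for surface area rows
AN-06,imaging_annotation,volume,outlier_percentile,,1,99,5,,,,Volume values beyond the 1st and 99th percentiles should be reviewed
AN-07,imaging_annotation,surface,outlier_percentile,,1,99,5,,,,Surface values beyond the 1st and 99th percentiles should be reviewed
AN-08,imaging_annotation,annotation_system,nonempty_text,100,,,,,,,Annotation system rows must carry a nonempty text value
AN-09,imaging_annotation,,co_presence,95,,,,,volume,annotation_text,A lesion with a volume row necessitates an annotation text row
FP-01,filepath,file_path,nonempty_text,100,,,,,,,File path must be nonempty
FP-02,filepath,file_size_bytes,nonmissing_numeric,100,,,,,,,File size must exist and be numeric
FP-03,filepath,file_size_bytes,outlier_percentile,,1,99,5,,,,File sizes beyond the 1st and 99th percentiles should be reviewed
FP-04,filepath,file_format,value_set,100,,,,dcm,,,File format token must be dcm
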