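category,weight,prefix
myocardial_infarction,1,I21
myocardial_infarction,1,I22
myocardial_infarction,1,I25.2
congestive_heart_failure,1,I50
peripheral_vascular_disease,1,I71
peripheral_vascular_disease,1,I73.9
peripheral_vascular_disease,1,I79.0
peripheral_vascular_disease,1,R02
peripheral_vascular_disease,1,Z95.8
peripheral_vascular_disease,1,Z95.9
cerebrovascular_disease,1,G45
cerebrovascular_disease,1,G46
cerebrovascular_disease,1,I60
cerebrovascular_disease,1,I61
cerebrovascular_disease,1,I62
cerebrovascular_disease,1,I63
cerebrovascular_disease,1,I64
cerebrovascular_disease,1,I65
cerebrovascular_disease,1,I66
cerebrovascular_disease,1,I67
cerebrovascular_disease,1,I68
cerebrovascular_disease,1,I69
dementia,1,F00
dementia,1,F01
dementia,1,F02
dementia,1,F05.1
chronic_pulmonary_disease,1,J40
chronic_pulmonary_disease,1,J41
chronic_pulmonary_disease,1,J42
chronic_pulmonary_disease,1,J43
chronic_pulmonary_disease,1,J44
chronic_pulmonary_disease,1,J45
chronic_pulmonary_disease,1,J46
chronic_pulmonary_disease,1,J47
chronic_pulmonary_disease,1,J60
chronic_pulmonary_disease,1,J61
chronic_pulmonary_disease,1,J62
chronic_pulmonary_disease,1,J63
chronic_pulmonary_disease,1,J64
chronic_pulmonary_disease,1,J65
chronic_pulmonary_disease,1,J66
chronic_pulmonary_disease,1,J67
rheumatic_disease,1,M05
rheumatic_disease,1,M06
rheumatic_disease,1,M32
rheumatic_disease,1,M33
rheumatic_disease,1,M34
rheumatic_disease,1,M35.3
peptic_ulcer_disease,1,K25
peptic_ulcer_disease,1,K26
peptic_ulcer_disease,1,K27
peptic_ulcer_disease,1,K28
mild_liver_disease,1,K70
mild_liver_disease,1,K71.7
mild_liver_disease,1,K73
mild_liver_disease,1,K74
diabetes,1,E10
diabetes,1,E11
diabetes,1,E12
diabetes,1,E13
diabetes,1,E14
diabetes_with_complications,2,E10.2
diabetes_with_complications,2,E10.3
diabetes_with_complications,2,E10.4
diabetes_with_complications,2,E10.5
diabetes_with_complications,2,E10.6
diabetes_with_complications,2,E10.7
diabetes_with_complications,2,E11.2
diabetes_with_complications,2,E11.3
diabetes_with_complications,2,E11.4
diabetes_with_complications,2,E11.5
diabetes_with_complications,2,E11.6
diabetes_with_complications,2,E11.7
diabetes_with_complications,2,E12.2
diabetes_with_complications,2,E12.3
diabetes_with_complications,2,E12.4
diabetes_with_complications,2,E12.5
diabetes_with_complications,2,E12.6
diabetes_with_complications,2,E12.7
diabetes_with_complications,2,E13.2
diabetes_with_complications,2,E13.3
diabetes_with_complications,2,E13.4
diabetes_with_complications,2,E13.5
diabetes_with_complications,2,E13.6
diabetes_with_complications,2,E13.7
diabetes_with_complications,2,E14.2
diabetes_with_complications,2,E14.3
diabetes_with_complications,2,E14.4
diabetes_with_complications,2,E14.5
diabetes_with_complications,2,E14.6
diabetes_with_complications,2,E14.7
hemiplegia_paraplegia,2,G81
hemiplegia_paraplegia,2,G82
renal_disease,2,I12.0
renal_disease,2,I13.1
renal_disease,2,N05.2
renal_disease,2,N05.3
renal_disease,2,N05.4
renal_disease,2,N05.5
renal_disease,2,N05.6
renal_disease,2,N05.7
renal_disease,2,N18
renal_disease,2,N19
renal_disease,2,N25.0
renal_disease,2,Z49
renal_disease,2,Z94.0
renal_disease,2,Z99.2
malignancy,2,C0
malignancy,2,C1
malignancy,2,C2
malignancy,2,C30
malignancy,2,C31
malignancy,2,C32
malignancy,2,C33
malignancy,2,C34
malignancy,2,C37
malignancy,2,C38
malignancy,2,C39
malignancy,2,C40
malignancy,2,C41
malignancy,2,C43
malignancy,2,C45
malignancy,2,C46
malignancy,2,C47
malignancy,2,C48
malignancy,2,C49
malignancy,2,C50
malignancy,2,C51
malignancy,2,C52
malignancy,2,C53
malignancy,2,C54
malignancy,2,C55
malignancy,2,C56
malignancy,2,C57
malignancy,2,C58
malignancy,2,C60
malignancy,2,C61
malignancy,2,C62
malignancy,2,C63
malignancy,2,C64
malignancy,2,C65
malignancy,2,C66
malignancy,2,C67
malignancy,2,C68
malignancy,2,C69
malignancy,2,C70
malignancy,2,C71
malignancy,2,C72
malignancy,2,C73
malignancy,2,C74
malignancy,2,C75
malignancy,2,C76
malignancy,2,C81
malignancy,2,C82
malignancy,2,C83
malignancy,2,C84
malignancy,2,C85
malignancy,2,C88
malignancy,2,C90
malignancy,2,C91
malignancy,2,C92
malignancy,2,C93
malignancy,2,C94
malignancy,2,C95
malignancy,2,C96
malignancy,2,C97
moderate_severe_liver_disease,3,I85.0
moderate_severe_liver_disease,3,I85.9
moderate_severe_liver_disease,3,I86.4
moderate_severe_liver_disease,3,I98.2
moderate_severe_liver_disease,3,K70.4
moderate_severe_liver_disease,3,K71.1
moderate_severe_liver_disease,3,K72.1
moderate_severe_liver_disease,3,K72.9
moderate_severe_liver_disease,3,K76.5
moderate_severe_liver_disease,3,K76.6
moderate_severe_liver_disease,3,K76.7
metastatic_solid_tumour,6,C77
metastatic_solid_tumour,6,C78
metastatic_solid_tumour,6,C79
metastatic_solid_tumour,6,C80
aids_hiv,6,B20
aids_hiv,6,B21
aids_hiv,6,B22
aids_hiv,6,B23
aids_hiv,6,B24
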