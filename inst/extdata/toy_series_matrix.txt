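!Series_title	"Toy liver expression series"
!Series_geo_accession	"GSE0000"
!Sample_title	"liver_1"	"liver_2"	"liver_3"
!series_matrix_table_begin
"ID_REF"	"GSM001"	"GSM002"	"GSM003"
"EPCAM"	120.5	340.2	98.1
"GPC3"	80.0	75.5	410.9
"FST"	55.1	60.3	57.8
"SOX9"	200.0	210.4	190.7
"AFP"	1500.2	1620.8	1390.6
!series_matrix_table_end
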