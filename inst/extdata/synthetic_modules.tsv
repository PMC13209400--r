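module_id	step_index	kos
M_vent_heme	1	K90100
M_vent_heme	2	K90101,K90152
M_vent_heme	3	K90102
M_vent_heme	4	K90103
M_vent_heme	5	K90104
M_vent_gcs	1	K90200
M_vent_gcs	2	K90201
M_vent_gcs	3	K90202
M_vent_gcs	4	K90203
M_vent_lip	1	K90300
M_vent_lip	2	K90301
M_vent_lip	3	K90302
M_house_info	1	K90400
M_house_info	2	K90401
M_house_info	3	K90402
M_house_info	4	K90403
M_house_info	5	K90404,K90455
M_house_info	6	K90405
M_house_energy	1	K90500
M_house_energy	2	K90501
M_house_energy	3	K90502
M_house_energy	4	K90503
M_house_energy	5	K90504
M_variable	1	K90600
M_variable	2	K90601
M_variable	3	K90602
M_variable	4	K90603
M_variable	5	K90604
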