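sample_id	variety	condition	replicate
res_cold_1	resistant	cold	1
res_cold_2	resistant	cold	2
res_cold_3	resistant	cold	3
res_control_1	resistant	control	1
res_control_2	resistant	control	2
res_control_3	resistant	control	3
sus_cold_1	susceptible	cold	1
sus_cold_2	susceptible	cold	2
sus_cold_3	susceptible	cold	3
sus_control_1	susceptible	control	1
sus_control_2	susceptible	control	2
sus_control_3	susceptible	control	3
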