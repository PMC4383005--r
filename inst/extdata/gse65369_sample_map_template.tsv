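sample	stage	population
GSM_REPLACE_ME_01	ES	unsorted
GSM_REPLACE_ME_02	NE	HES5+
GSM_REPLACE_ME_03	NE	HES5-
GSM_REPLACE_ME_04	E-RG	HES5+
GSM_REPLACE_ME_05	E-RG	HES5-
GSM_REPLACE_ME_06	M-RG	HES5+
GSM_REPLACE_ME_07	M-RG	HES5-
GSM_REPLACE_ME_08	L-RG	HES5+
GSM_REPLACE_ME_09	L-RG	HES5-
GSM_REPLACE_ME_10	LNP	HES5+
GSM_REPLACE_ME_11	LNP	HES5-
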