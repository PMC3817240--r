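# Descriptive category counts for the emulated Chinese prostate-cancer
# case-control cohort (1417 hospital-based cases, 1008 healthy controls).
# Percentages in the published table are taken among subjects with a
# non-missing value: 100 * count / (total - missing). For clinical-stage
# variables the missing count is the remainder total - sum(category counts).
group	variable	category	count	total	missing
case	psa	le4	55	1417	78
case	psa	gt4_lt10	186	1417	78
case	psa	ge10	1098	1417	78
control	psa	le4	965	1008	2
control	psa	gt4_lt10	32	1008	2
control	psa	ge10	9	1008	2
case	gleason	lt7	355	1417	69
case	gleason	ge7	993	1417	69
case	stage	stage_0_I_II	727	1417	200
case	stage	stage_III_IV	490	1417	200
case	n_stage	n0	759	1417	289
case	n_stage	n_ge1	369	1417	289
case	m_stage	m0	810	1417	167
case	m_stage	m_ge1	440	1417	167
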