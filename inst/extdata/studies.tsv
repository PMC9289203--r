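trait	consortium	n_cases	n_controls	n_total	ancestry
CEC	NA	NA	NA	5293	European
CAD	CARDIoGRAMplusC4D	60801	123504	184305	European
MI	CARDIoGRAMplusC4D	43677	128199	171876	European
IS	MEGASTROKE	40585	406111	446696	European
LAS	MEGASTROKE	34217	406111	440328	European
SVS	MEGASTROKE	5386	406111	411497	European
CES	MEGASTROKE	7193	406111	413304	European
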