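scenario	ligand	allele	mu_nm	se_printed_nm	theta_per_ps	sigma_nm_sqrtps	x0_nm	switch_t_ps	switch_mu_nm
dextromethorphan:*1	dextromethorphan	*1	0.439	0.002	0.2	0.049134	0.439	NA	NA
dextromethorphan:*14A	dextromethorphan	*14A	0.518	0.003	0.2	0.062565	0.518	NA	NA
dextromethorphan:*51	dextromethorphan	*51	1.157	0.001	0.2	0.044721	1.157	NA	NA
bufuralol:*1	bufuralol	*1	0.407	0.001	0.2	0.043694	0.407	NA	NA
bufuralol:*14A	bufuralol	*14A	0.659	0.002	0.2	0.086538	0.659	NA	NA
bufuralol:*51	bufuralol	*51	0.535	0.001	0.2	0.044721	0.535	NA	NA
OTA:*1	OTA	*1	0.501	0.001	0.2	0.044721	0.501	NA	NA
OTA:*14A	OTA	*14A	0.628	0.001	0.2	0.044721	0.628	NA	NA
OTA:*51	OTA	*51	0.72	0.001	0.2	0.044721	0.72	NA	NA
OTA:*110	OTA	*110	0.448	0.001	0.2	0.044721	0.448	NA	NA
OTA:*122	OTA	*122	0.501	NA	0.2	0.044721	0.501	5000	1.2
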