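roi	metric	intercept	beta_age	beta_age2	beta_sex	beta_hemi	noise_sd0	noise_sd_slope	network_id	network_loading
Cau	R1	0.93	0.00384	-4e-05	0.01	0.008	0.025	0.0002	A	0.02
Pu	R1	0.98	0.0044	-4e-05	0.01	0.008	0.025	0.0002	A	0.02
GPe	R1	1.15	0.00464	-4e-05	0.01	0.008	0.025	0.0002	B	0.02
GPi	R1	1.18	0.0048	-4e-05	0.01	0.008	0.025	0.0002	B	0.02
NAcc	R1	0.9	0.0018	-1e-05	0.01	0.012	0.03	0.0002	none	0
SNc	R1	1.05	0.004	-4e-05	0.01	0.01	0.028	0.0002	B	0.02
SNr	R1	1.08	0.00416	-4e-05	0.01	0.01	0.028	0.0002	B	0.02
RN	R1	1.02	0.00448	-4e-05	0.01	0.008	0.028	0.0002	B	0.02
STN	R1	1.06	0.00432	-4e-05	0.01	0.008	0.03	0.0002	B	0.02
VP	R1	1.1	0.0018	-1e-05	0.01	0.008	0.03	0.0002	B	0.02
Cau	R2star	16	0.12	0	0.5	0.3	1.5	0.01	A	1.3
Pu	R2star	18	0.25	0	0.5	0.3	1.5	0.01	A	1.3
GPe	R2star	45	0.08	0	0.5	0.3	2	0.01	B	1.6
GPi	R2star	43	0.08	0	0.5	0.3	2	0.01	B	1.6
NAcc	R2star	14	0.05	0	0.5	0.4	1.8	0.01	none	0
SNc	R2star	30	0.15	0	0.5	0.3	2	0.01	B	1.6
SNr	R2star	33	0.15	0	0.5	0.3	2	0.01	B	1.6
RN	R2star	28	0.18	0	0.5	0.3	2	0.01	B	1.6
STN	R2star	32	0.12	0	0.5	0.3	2.2	0.01	B	1.6
VP	R2star	26	0.08	0	0.5	0.3	2.2	0.01	B	1.6
Cau	chi	0.04	0.0005	0	0.002	0.001	0.008	5e-05	A	0.007
Pu	chi	0.02	0.0012	0	0.002	0.001	0.008	5e-05	A	0.007
GPe	chi	0.12	0.0003	0	0.002	0.001	0.01	5e-05	B	0.008
GPi	chi	0.11	0.0003	0	0.002	0.001	0.01	5e-05	B	0.008
NAcc	chi	0.02	0.0003	0	0.002	0.0015	0.009	5e-05	none	0
SNc	chi	0.08	0.0008	0	0.002	0.001	0.01	5e-05	B	0.008
SNr	chi	0.09	0.0008	0	0.002	0.001	0.01	5e-05	B	0.008
RN	chi	0.06	0.0009	0	0.002	0.001	0.01	5e-05	B	0.008
STN	chi	0.07	0.0007	0	0.002	0.001	0.011	5e-05	B	0.008
VP	chi	0.05	0.0004	0	0.002	0.001	0.011	5e-05	B	0.008
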