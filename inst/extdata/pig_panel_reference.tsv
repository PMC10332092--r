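chrom	n_probes	mean_density	mean_coverage_kb	mean_interprobe_mb	mean_dist_ends_mb
SSC1	11	7.95	407.14	25.62	6.83
SSC2	6	7.02	472.20	27.13	6.73
SSC3	5	6.51	489.77	29.35	6.50
SSC4	5	7.51	435.29	28.82	6.74
SSC5	4	5.54	567.71	29.91	6.26
SSC6	6	7.83	417.29	30.99	6.70
SSC7	5	7.47	422.50	26.61	6.64
SSC8	5	6.50	529.61	30.93	6.29
SSC9	5	6.91	462.63	31.04	6.52
SSC10	3	8.62	392.15	27.68	6.41
SSC11	3	6.84	467.41	32.60	6.28
SSC12	3	6.07	529.09	23.61	6.39
SSC13	11	7.38	317.05	18.57	9.55
SSC14	5	7.24	421.43	31.54	6.74
SSC15	5	7.47	440.67	31.21	6.68
SSC16	3	7.63	410.37	32.91	6.45
SSC17	3	7.50	421.36	24.78	6.33
SSC18	3	6.09	524.97	20.90	6.31
SSCX	4	6.34	517.71	35.41	8.82
SSCY	2	3.02	524.80	29.41	6.55
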