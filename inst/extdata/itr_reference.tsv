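epoch_length_ms	condition	s1	s2	s3	s4	s5	printed_average	rounding_anomaly
160	calibrated	31.3	35.8	35.8	31.3	27.5	32.3	FALSE
140	calibrated	28.7	34.2	34.2	27.5	27.5	30.4	FALSE
120	calibrated	28.7	34.2	34.2	27.5	25.2	29.9	TRUE
100	calibrated	28.7	31.3	31.3	23.0	25.2	27.9	FALSE
80	calibrated	28.7	29.9	28.7	20.1	24.1	26.3	FALSE
60	calibrated	21.1	26.3	29.9	15.8	16.7	22.0	FALSE
160	fixed	22.0	25.2	34.2	16.7	16.7	22.9	TRUE
140	fixed	23.0	26.3	34.2	18.3	21.1	24.6	FALSE
120	fixed	22.0	26.3	34.2	19.2	24.1	25.2	FALSE
100	fixed	21.1	26.3	29.9	17.5	26.3	24.2	FALSE
80	fixed	21.1	27.5	28.7	17.5	19.2	22.8	FALSE
60	fixed	20.1	23.0	20.1	15.8	15.8	19.0	FALSE
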