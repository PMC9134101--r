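peptide	antigen_class	sample_id	endogenous_ratio	mean_intensity	sps_ms3_ratio	calibration_r2
RMLLSHTGK	aeTSA	RKO	NA	NA	NA	NA
LPHRALSGI	aeTSA	S1	-0.364	NA	NA	NA
GTNPTAAVK	aeTSA	S2	2.095	7238.425242	12.174	1.000
LRHKLVLNR	aeTSA	S2	0.307	NA	NA	NA
RIGGVGVEK	aeTSA	S2	1.965	29256.45	6.740	1.000
SIIETVNSL	aeTSA	S2	0.288	NA	NA	NA
TVNTQQYNTK	aeTSA	S2	-0.021	NA	NA	NA
SVSHLHIFF	aeTSA	S3	-1.100	NA	NA	NA
TTLENLPQK	aeTSA	S4	0.134	3140.8875	3.783	0.999
AQKLQVRI	aeTSA	S5	0.793	NA	NA	NA
GQIELSIYR	aeTSA	S5	0.328	NA	NA	NA
HGALSIRSI	aeTSA	S5	0.777	NA	NA	NA
RLMKFLPV	aeTSA	S5	0.171	NA	NA	NA
SLYISEERK	aeTSA	S5	0.046	NA	NA	NA
VQTAVLNV	aeTSA	S5	1.089	NA	NA	NA
VEAPHLPSF	aeTSA	S6	1.059	43782.84192	41.318	1.000
RNRQVATAL	aeTSA	S6	1.090	12174.6625	5.722	1.000
RNRQVATAL	not_assigned	S1	0.890	15514.2375	3.507	1.000
KIGEVIVTK	mTSA	S2	2.506	70659.61	3.637	1.000
TRSTIILHL	mTSA	S3	1.381	34365.32187	48.807	0.997
VLYRSVLLLK	TAA_noncanonical	S6	0.997	NA	NA	NA
TYKYVDINTF	TAA_canonical	S1	1.969	29834.36875	8.226	0.998
RYLEKFYGL	TAA_canonical	S1	2.840	27614.24286	7.661	0.997
RYLEKFYGL	TAA_canonical	S6	2.970	106928.2875	16.090	0.999
KSINEFWNK	TAA_canonical	S2	2.212	56110.11667	5.238	0.999
RIQLPVVSK	TAA_canonical	S4	1.083	7612.37857	12.073	0.999
QMAGLRDTY	TAA_canonical	S3	1.140	36090.60294	2.884	0.999
AQYDQASTKY	TAA_canonical	S4	1.452	NA	NA	NA
FVDNQYWRY	TAA_canonical	S4	0.721	5853.986533	10.954	1.000
SANVSKVSF	TAA_canonical	S5	1.114	12780.925	2.321	0.999
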