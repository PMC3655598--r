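peptide_id	n_aa	sequence	hla_motifs	cluster_score	igg_location
hTregitope-167	26	PAVLQSSGLYSLSSVVTVPSSSLGTQ	20	30.05	CH1
hTregitope-289	21	EEQYNSTYRVVSVLTVLHQDW	14	22.57	CH2
mTregitope-167	20	PAVLQSDLYTLSSSVTVPSS	NA	NA	CH1
mTregitope-289	18	EEQFNSTFRSVSELPIMHQ	NA	NA	CH2
mPPI_7-23	17	FLPLLALLALWEPKPTQ	11	18.69	NA
mPPI_20-35	16	KPTQAFVKQHLCGPHL	2	-2.82	NA
mPPI_33-47	15	PHLVEALYLVCGERG	3	-0.69	NA
mPPI_71-86	16	SPGDLQTLALEVARQK	0	-6.59	NA
mPPI_77-92	16	TLALEVARQKRGIVDQ	2	-3.1	NA
TetTox_830-844	15	QYIKANSKFIGITEL	13	25.65	NA
Flu-HA_308-318	13	PRYVKQNTLKLAT	10	21.82	NA
OVA_323-339	17	KISQAVHAAHAEINEAG	4	-0.39	NA
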