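Gene name	Mutation AA	Sample name
TP53	p.M273V	UCEC-S00001
TP53	p.M273*	UCEC-S00002
TP53	p.M273_P275del	UCEC-S00003
TP53	p.G248P	UCEC-S00004
TP53	p.G248*	UCEC-S00005
PTEN	p.I130T	UCEC-S00006
PTEN	p.I130*	UCEC-S00007
PTEN	p.M173V	UCEC-S00008
CTNNB1	p.C45K	UCEC-S00009
CTNNB1	p.C45*	UCEC-S00010
NFE2L2	p.H29S	UCEC-S00011
NFE2L2	p.H29*	UCEC-S00012
NFE2L2	p.Y79Q	UCEC-S00013
NFE2L2	p.Y79*	UCEC-S00014
NFE2L2	p.Y79_A81del	UCEC-S00015
NFE2L2	p.R82H	UCEC-S00016
IDH1	p.K132Y	UCEC-S00017
EGFR	p.Q746M	UCEC-S00018
TP53	p.Q6M	UCEC-S00019
TP53	p.Y19Q	UCEC-S00020
TP53	p.R22H	UCEC-S00021
PTEN	p.D124L	UCEC-S00022
PTEN	p.E47F	UCEC-S00023
PTEN	p.F234A	UCEC-S00024
PTEN	p.P75R	UCEC-S00025
PTEN	p.F294A	UCEC-S00026
PTEN	p.K392Y	UCEC-S00027
CTNNB1	p.T77D	UCEC-S00028
CTNNB1	p.Y699Q	UCEC-S00029
CTNNB1	p.T577D	UCEC-S00030
CTNNB1	p.W98C	UCEC-S00031
CTNNB1	p.M113V	UCEC-S00032
CTNNB1	p.Y519Q	UCEC-S00033
CTNNB1	p.P15R	UCEC-S00034
NFE2L2	p.I150T	UCEC-S00035
NFE2L2	p.Q86M	UCEC-S00036
NFE2L2	p.N143I	UCEC-S00037
NFE2L2	p.F514A	UCEC-S00038
NFE2L2	p.N223I	UCEC-S00039
BRAF	p.N543I	UCEC-S00040
BRAF	p.M713V	UCEC-S00041
BRAF	p.H669S	UCEC-S00042
BRAF	p.R222H	UCEC-S00043
BRAF	p.R202H	UCEC-S00044
BRAF	p.R582H	UCEC-S00045
BRAF	p.I530T	UCEC-S00046
BRAF	p.K432Y	UCEC-S00047
BRAF	p.K92Y	UCEC-S00048
IDH1	p.I310T	UCEC-S00049
IDH1	p.I170T	UCEC-S00050
IDH1	p.Q366M	UCEC-S00051
IDH1	p.H409S	UCEC-S00052
IDH1	p.G268P	UCEC-S00053
IDH1	p.E287F	UCEC-S00054
KIT	p.H849S	UCEC-S00055
KIT	p.T617D	UCEC-S00056
EGFR	p.S756N	UCEC-S00057
EGFR	p.E387F	UCEC-S00058
EGFR	p.K92Y	UCEC-S00059
EGFR	p.D1204L	UCEC-S00060
EGFR	p.V1160E	UCEC-S00061
EGFR	p.M433V	UCEC-S00062
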