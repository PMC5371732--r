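# Default amino-acid profile table for the fasting-state liver boundary model.
# The network lumps amino acids into six explicit species (ala, gln, glu, gly,
# ser, cys) plus a pooled remainder (aax). Columns:
#   muscle_fraction      relative molar share of fasting muscle AA release;
#                        glutamine + alanine sum to 0.60 by calibration
#   adipose_conc_umol_l  adipose veno-arterial concentration difference (umol/l)
#   liver_molar_ratio    molar AA composition of liver protein (autophagy input
#                        and apoB pseudo-protein composition)
#   molar_mass           g/mol (aax uses the pooled mean of 136.5)
#   carbons              carbon atoms per molecule (aax uses the pooled mean)
aa	muscle_fraction	adipose_conc_umol_l	liver_molar_ratio	molar_mass	carbons
ala	0.30	14.0	0.09	89.09	3
gln	0.30	16.0	0.05	146.15	5
glu	0.04	2.5	0.09	147.13	5
gly	0.07	7.0	0.10	75.07	2
ser	0.05	5.0	0.06	105.09	3
cys	0.02	1.5	0.02	121.16	3
aax	0.22	10.0	0.59	136.50	5
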