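monomer_id	class	formula	molar_mass
ala	amino_acid	C3H7NO2	89.094
arg	amino_acid	C6H14N4O2	174.204
asn	amino_acid	C4H8N2O3	132.119
asp	amino_acid	C4H7NO4	133.103
cys	amino_acid	C3H7NO3	105.093
gln	amino_acid	C5H10N2O3	146.146
glu	amino_acid	C5H9NO4	147.13
gly	amino_acid	C2H5NO2	75.067
hist	amino_acid	C6H9N3O2	155.157
ile	amino_acid	C6H13NO2	131.175
leu	amino_acid	C6H13NO2	131.175
lys	amino_acid	C6H14N2O2	146.19
met	amino_acid	C5H11NO3	133.147
phe	amino_acid	C9H11NO2	165.192
pro	amino_acid	C5H9NO2	115.132
ser	amino_acid	C3H7NO3	105.093
thr	amino_acid	C4H9NO3	119.12
trp	amino_acid	C11H12N2O2	204.229
tyr	amino_acid	C9H11NO3	181.191
val	amino_acid	C5H11NO2	117.148
glucose	sugar	C6H12O6	180.156
galac	sugar	C6H12O6	180.156
mann	sugar	C6H12O6	180.156
xylu	sugar	C5H10O5	150.13
arab	sugar	C5H10O5	150.13
fuco	sugar	C6H12O5	164.157
rhamn	sugar	C6H12O5	164.157
glucur	sugar	C6H10O7	194.139
mannsul	sugar	C6H12O9	228.153
lip01	lipid	C35H60N1O7P1	637.839
lip02	lipid	C36H62N1O8P1	667.865
lip03	lipid	C37H64N1O6P1	649.894
lip04	lipid	C38H66N1O7P1	679.92
lip05	lipid	C39H68O8P1	695.939
lip06	lipid	C40H70O6P1	677.968
lip07	lipid	C41H72O7P1	707.994
lip08	lipid	C42H74O8P1	738.02
lip09	lipid	C43H76O6	689.075
lip10	lipid	C44H78O7	719.101
lip11	lipid	C45H80O8	749.127
lip12	lipid	C46H82O6	731.156
lip13	lipid	C47H84O7	761.182
lip14	lipid	C48H86O8	791.208
lip15	lipid	C49H88O6	773.237
lip16	lipid	C50H90O7	803.263
lip17	lipid	C51H92O8	833.289
lip18	lipid	C52H94O6	815.318
lip19	lipid	C53H96O7	845.344
tag	tag	C55H98O6	855.383
chla	pigment	C55H72N4O5	869.204
chlc	pigment	C35H30N4O5	586.648
fucoxan	pigment	C42H58O6	658.92
bcarot	pigment	C40H56	536.888
dd	pigment	C40H54O3	582.869
damp	dna	C10H14N5O6P	331.225
dcmp	dna	C9H14N3O7P	307.199
dgmp	dna	C10H14N5O7P	347.224
dtmp	dna	C10H15N2O8P	322.21
amp	rna	C10H14N5O7P	347.224
cmp	rna	C9H14N3O8P	323.198
gmp	rna	C10H14N5O8P	363.223
ump	rna	C9H13N2O9P	324.182
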