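chla: 0.14
chlc: 0.03
fucoxan: 0.06
bcarot: 0.004
dd: 0.009
gcprop: 40.0
genomesize: 6.1e+07
rnadna: 8.0
lip01: 0.12
lip02: 0.1
lip03: 0.09
lip04: 0.08
lip05: 0.07
lip06: 0.06
lip07: 0.055
lip08: 0.05
lip09: 0.045
lip10: 0.04
lip11: 0.035
lip12: 0.03
lip13: 0.028
lip14: 0.025
lip15: 0.022
lip16: 0.02
lip17: 0.016
lip18: 0.013
lip19: 0.01
ala: 0.07
arg: 0.048
asn: 0.03
asp: 0.075
cys: 0.008
gln: 0.03
glu: 0.08
gly: 0.05
hist: 0.015
ile: 0.035
leu: 0.065
lys: 0.045
met: 0.018
phe: 0.04
pro: 0.04
ser: 0.045
thr: 0.04
trp: 0.01
tyr: 0.025
val: 0.045
totalprot: 0.46
totalcarb: 0.31
totallip: 0.21
totaldna: 0.0022
totalrna: 0.018
totalpigm: 0.016
propglu: 30.0
proptga: 20.0
glucose: 0.0
galac: 0.12
mann: 0.22
xylu: 0.1
arab: 0.11
fuco: 0.15
rhamn: 0.13
glucur: 0.1
mannsul: 0.32
cn: 5.7
np: 10.0
ps: 0.78
ccell: 7.5
dwcell: 15.0
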