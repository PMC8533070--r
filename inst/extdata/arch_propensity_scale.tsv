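# Synthetic beta-aggregation propensity scale used by the bundled
# simplified stand-in arch scorer. Values are package conventions in
# [0, 1] that follow the broad trends of published beta-aggregation
# scales (hydrophobics and Q/N high; P, E, D, K low); they do NOT
# reproduce any external predictor. X carries the scale mean.
A	0.50
C	0.60
D	0.15
E	0.10
F	0.85
G	0.40
H	0.40
I	0.90
K	0.20
L	0.80
M	0.65
N	0.75
P	0.05
Q	0.75
R	0.25
S	0.45
T	0.55
V	0.85
W	0.70
Y	0.75
X	0.53
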