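# Synthetic disorder propensity scale used by the bundled simplified
# stand-in disorder scorer. Values are package conventions in [0, 1]
# following the usual disorder/order-promoting residue ranking
# (P, E, K, S, Q, G high; W, F, Y, I, L, V low); they do NOT reproduce
# any external predictor. X carries the scale mean.
A	0.70
C	0.30
D	0.75
E	0.90
F	0.15
G	0.76
H	0.45
I	0.20
K	0.85
L	0.22
M	0.35
N	0.50
P	0.95
Q	0.78
R	0.72
S	0.80
T	0.55
V	0.25
W	0.10
Y	0.18
X	0.53
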