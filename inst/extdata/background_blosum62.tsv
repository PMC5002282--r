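aa	freq
A	0.078047
R	0.051269
N	0.044873
D	0.053640
C	0.019246
Q	0.042644
E	0.062949
G	0.073802
H	0.021992
I	0.051420
L	0.090191
K	0.057438
M	0.022425
F	0.038556
P	0.052028
S	0.071198
T	0.058413
W	0.013298
Y	0.032165
V	0.064409
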