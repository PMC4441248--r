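haplogroup	n_sequences	mean_mutations_to_root
E1b-M35	13	65
G2a-L31	18	61
I1-M253	46	13
I2-P215	30	64
J2-M172	23	80
J2a-M410	15	58
J2b-M102	8	42
N1c-M178	13	18
R1a-M198	25	24
R1b-M269	144	18
R1b-L11	131	13
R1b-S116	100	12
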