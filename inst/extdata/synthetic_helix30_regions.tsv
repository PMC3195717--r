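# synthetic 30-residue helix: example region table
1	10	N-lobe
11	20	C-lobe
21	25	ACT1
26	30	ACT2
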