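# MP2RAGEME: inversion-recovery dual-block GRE, multi-echo second block
name: MP2RAGEME
tr_cycle: 6.72        # s, between inversions
tr_block1: 6.2        # ms
tr_block2: 31.4       # ms
te1: 3                # ms
te2: [3, 11.5, 20, 28.5]
ti1: 670              # ms, inversion to centre of block 1
ti2: 3855             # ms
alpha1: 7             # degrees
alpha2: 6
n_lines: 150
n_readouts: 147
inv_efficiency: 1.0
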