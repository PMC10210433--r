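# Standard parameter set of the equilibrium phase diagrams.
N = 20
beta = 0.95
s = 0.3
B = 1.435
C_G = 0.1
C_C = 0.2
mu = 0
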