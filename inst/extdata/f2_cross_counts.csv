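cross,wild,mutant
KF1_x_mutant,650,42
NN1138-2_x_mutant,420,120
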