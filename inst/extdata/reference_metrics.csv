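algorithm,sensitivity,accuracy
MLP,0.700,0.753
RF,0.703,0.748
J48,0.694,0.751
ASJ48,0.688,0.750
ASKNN,0.701,0.735
ASMLP,0.684,0.746
ASRF,0.692,0.731
KNN,0.685,0.728
NB,0.647,0.739
ASNB,0.638,0.735
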