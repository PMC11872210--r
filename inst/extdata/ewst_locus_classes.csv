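locus,genotype,n_hybrid,n_allopolyploid
MS02,268,7,63
MS02,257/268,0,9
MS07,257,1,1
MS07,257/273,6,71
MS13,248,0,1
MS13,248/264,6,67
MS13,238/248/264,1,4
MS14,271,7,69
MS14,260/271,0,2
MS14,268/271,0,1
MS15,250,1,0
MS15,223/250/261,1,5
MS15,223/242/250/258,0,1
MS15,223/250/258/261,5,66
MS16,204/251/260,7,72
MS17,264,0,3
MS17,264/273,7,69
MS18,260,7,61
MS18,245/260,0,1
MS18,245/288,0,1
MS18,250/260,0,7
MS18,260/280,0,2
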