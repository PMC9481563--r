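dist(TyrO2P-Ala461N) = 3.1 (-0.2 + 0.3)
dist(TyrO1P-Ile463N) = 3.2 (-0.7 + 0.1)
dist(TyrO1P-Gly464N) = 2.9 (-0.3 + 0.4)
dist(TyrO3P-Arg465N) = 2.9 (-0.3 + 0.2)
dist(TyrCB-38CG) = 3.8 (-0.4 + 0.1)
dist(TyrCB-Ile282CG1) = 3.7 (-0.3 + 1.6)
dist(GlyO-Lys280N) = 3.3 (-0.5 + 0.8)
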