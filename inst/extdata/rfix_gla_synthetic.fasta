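>rFIX_GLA_synthetic mature factor IX N-terminal region (GLA domain + start of EGF-like 1), synthetic sequence assembled from tryptic/GluC peptides; 1-based mature numbering
YNSGKLEEFVQGNLERECMEEKCSFEEAREVFENTERTTEFWKQYVDGDQCE
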