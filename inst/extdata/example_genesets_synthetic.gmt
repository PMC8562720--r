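hypoxia_synthetic	synthetic example hypoxia-style gene set for demonstrations	LNC00101	LNC00102	LNC00103	LNC00104	LNC00105	LNC00106	LNC00107	LNC00108
caf_synthetic	synthetic example fibroblast-style gene set for demonstrations	LNC00201	LNC00202	LNC00203	LNC00204	LNC00205	LNC00206
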