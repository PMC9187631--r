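Affinity Capture-MS
Affinity Capture-Western
Co-crystal Structure
Reconstituted Complex
Biochemical Activity
Co-purification
Far Western
FRET
PCA
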