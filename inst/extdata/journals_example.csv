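name,impact_factor
JAMA,44.405
Nature,40.137
Science,37.205
Child's nervous system,1.081
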