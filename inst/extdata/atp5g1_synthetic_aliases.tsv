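ATP5G1	ATP5G1
ATP5G1	ATP5MC1
ATP5G1	Su9
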