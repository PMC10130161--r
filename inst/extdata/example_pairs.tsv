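reference	target
CK+	CD3+
CK+	CD68+
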