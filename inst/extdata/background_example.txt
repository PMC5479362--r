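# example prior knowledge: nothing can cause the burning regime
forbid * -> B
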