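class,count
segregating,93
nonsegregating,87
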