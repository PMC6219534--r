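# freely available (pool) compounds for the toy network
P
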