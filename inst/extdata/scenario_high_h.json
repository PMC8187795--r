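{"h":[[1,0,-235.17786561264828],[0,1,0],[0,0,1]]}
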