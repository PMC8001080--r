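# curated (seed) chemical entities for the worked example
EX:0020
EX:0021
EX:0022
EX:0023
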