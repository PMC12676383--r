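101011001101110110100100111000101111001010001100001000001111110
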