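targets, factors
x1, (x1 & !x2 & x3) | (x1 & x2 & !x3) | (x1 & x2 & x3)
x2, (x1 & !x2 & x3) | (x1 & x2 & !x3) | (x1 & x2 & x3)
x3, (!x1 & x2 & x3) | (x1 & !x2 & !x3) | (x1 & !x2 & x3) | (x1 & x2 & !x3) | (x1 & x2 & x3)
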