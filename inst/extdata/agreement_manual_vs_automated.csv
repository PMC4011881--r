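tier,high_positive,positive,low_positive,negative
high_positive,250,22,0,0
positive,17,416,43,0
low_positive,0,39,327,16
negative,0,1,12,177
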