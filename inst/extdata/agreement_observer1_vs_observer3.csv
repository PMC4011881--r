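tier,high_positive,positive,low_positive,negative
high_positive,0,0,0,0
positive,0,33,2,0
low_positive,0,17,173,37
negative,0,0,7,111
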