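low,high,mode
3000,3400,CH stretch
2880,2895,CH2 asymmetric stretching
2929,2937,CH3 stretching
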