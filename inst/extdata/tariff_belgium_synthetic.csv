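term,dimension,level,value
constant,,,0.152
decrement,1,2,0.074
decrement,1,3,0.314
decrement,2,2,0.083
decrement,2,3,0.196
decrement,3,2,0.036
decrement,3,3,0.142
decrement,4,2,0.061
decrement,4,3,0.180
decrement,5,2,0.054
decrement,5,3,0.090
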