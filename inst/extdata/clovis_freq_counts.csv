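region,k,f_k
East,1,60
East,2,15
East,3,7
East,4,4
East,5,1
East,6,1
West,1,48
West,2,8
West,3,7
West,4,2
West,7,1
West,8,1
West,10,1
West,11,1
West,12,1
West,13,1
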