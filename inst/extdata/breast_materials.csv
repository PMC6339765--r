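name,c10_pa,c01_pa,e_pa
fat,2000,1333,20000
fibroglandular,3500,2333.3,35000
tumor,10000,6667,100000
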