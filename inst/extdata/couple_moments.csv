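# n: 282
variable,stress_w,stress_h,dep_w,dep_h
stress_w,1,0.212,0.629,0.132
stress_h,0.212,1,0.168,0.482
dep_w,0.629,0.168,1,0.208
dep_h,0.132,0.482,0.208,1
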