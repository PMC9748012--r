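time_h,activity_MBq,u_activity_MBq,method
43.0,7.88,0.10,proposed
115.1,3.58,0.05,proposed
163.7,2.02,0.05,proposed
43.0,10.74,1.91,recovery
115.1,4.80,0.84,recovery
163.7,2.96,0.52,recovery
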