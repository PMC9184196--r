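-0.0010735,0.00036412,0.00040395999999999997,2.0639999999999999e-05,0.00028480999999999998
0.00036412,-0.0015070000000000001,0.00083268999999999997,0.00016223,0.00014797000000000001
0.00040395999999999997,0.00083268999999999997,-0.0022450999999999999,0.00081831999999999998,0.00019013
2.0639999999999999e-05,0.00016223,0.00081831999999999998,-0.0016371000000000001,0.00063595999999999998
0.00028480999999999998,0.00014797000000000001,0.00019013,0.00063595999999999998,-0.0012589000000000001
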