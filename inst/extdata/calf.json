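{"reference_point":[0,0.1665],"forward_direction_deg":0,"parts":{"head":[[0,-0.1665],[0.333,-0.1665],[0.333,0.1665],[0,0.1665]],"anterior":[[-1,-0.5],[0,-0.5],[0,0.5],[-1,0.5]],"posterior":[[-2,-0.5],[-1,-0.5],[-1,0.5],[-2,0.5]]}}
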