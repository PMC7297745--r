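{"reference_point":[0,0],"forward_direction_deg":90,"parts":{"visual":[[0,0],[173.205080756888,100],[-173.205080756888,100]]}}
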