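visit_id,om_considered
v001,true
v002,false
v003,false
v004,false
v005,false
v006,false
v007,true
v008,false
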