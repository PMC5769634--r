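label,x,y,z,radius
ABa,-12,0,0,9
ABp,0,0,8,9
EMS,0,0,-8,9
P2,14,0,0,9
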