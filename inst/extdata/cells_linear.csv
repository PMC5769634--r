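label,x,y,z,radius
ABa,-24,0,0,9
ABp,-8,0,0,9
EMS,8,0,0,9
P2,24,0,0,9
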