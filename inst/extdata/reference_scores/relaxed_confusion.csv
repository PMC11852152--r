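,ANAT,IMP,O,OBS-A,OBS-P,OBS-U
ANAT,784,0,0,0,0,1
IMP,0,339,1,1,4,0
O,11,0,1069,2,2,0
OBS-A,0,0,0,366,0,0
OBS-P,0,0,0,0,732,0
OBS-U,0,1,1,0,0,120
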