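label,tp,fp,fn
ANAT,710,87,102
IMP,307,75,83
OBS-A,206,16,9
OBS-P,719,191,206
OBS-U,91,18,21
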