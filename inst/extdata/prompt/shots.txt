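# One annotated example sentence per line; the raw input is the line with
# its tags stripped.
In the <span class="ANAT">right breast</span> there is <span class="OBS-P">nodular opacity</span>.
Within the <span class="ANAT">left axilla</span> we note <span class="OBS-A">no lymphadenopathy</span>.
Projecting over the <span class="ANAT">upper outer quadrant</span> examination shows <span class="OBS-U">a possible architectural distortion</span>.
IMPRESSION: <span class="IMP">BIRADS 2</span>.
In the <span class="ANAT">left breast</span> there is <span class="OBS-P">focal asymmetry</span> and <span class="OBS-A">no suspicious mass</span>.
Comparison was made with the prior examination.
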