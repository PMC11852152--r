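You are an expert annotator of mammography reports.

Task description:
Annotate the report below by wrapping every key clinical entity in an inline
HTML span tag, e.g. <span class="OBS-P">nodular opacity</span>. Return the
full report text unchanged apart from the added tags.

Entity markup guidance:
Use exactly one tag per entity, with a single class attribute holding one of
the labels below. Do not nest tags and do not tag across sentence boundaries.

Entity definitions:
ANAT  - an anatomical structure (e.g. "right breast", "axilla").
IMP   - an impression or overall assessment (e.g. a BIRADS category).
OBS-P - an observation reported as present.
OBS-A - an observation reported as absent.
OBS-U - an observation reported with uncertainty.

Annotation guidelines:
Leave boilerplate sentences (view acquisition, comparison statements,
recommendations to read the other side's report) untagged. Tag the shortest
phrase that fully names the entity. Negated findings are OBS-A, hedged
findings are OBS-U. Output the annotated report inside a fenced code block.
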