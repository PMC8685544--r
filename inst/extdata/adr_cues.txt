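#! name: adr_cues
#! mode: substring-stem
#! case_insensitive: true
# Reporting-verb cue phrases that mark attributable adverse-reaction
# statements in labeling prose. Combined with a liver-context gate these
# cues exactly identify hepatic-ADR sentences in the synthetic corpus
# (the solvable-by-construction oracle classifier).
been reported
was observed
were observed
have occurred
has occurred
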