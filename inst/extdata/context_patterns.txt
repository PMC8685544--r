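#! name: context_patterns
#! mode: substring-stem
#! case_insensitive: true
# Broad liver-context stems for the sentence-level string gate. Stems catch
# inflected and derived forms (hepat -> hepatic, hepatitis, hepatotoxicity).
# Short enzyme abbreviations use word-boundary mode to avoid firing inside
# unrelated words ("halt", "mast", ...).
hepat
liver
jaundice
bilirubin
transaminase
aminotransferase
cholestat
biliary
phosphatase
ALT	word-boundary
AST	word-boundary
SGPT	word-boundary
SGOT	word-boundary
ALP	word-boundary
GGT	word-boundary
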