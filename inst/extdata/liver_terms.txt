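#! name: liver_terms
#! mode: substring-stem
#! case_insensitive: true
# Token-level liver-term span patterns for the lexicon tagger. Each pattern
# token matches a word token by prefix (stem mode) or equality
# (word-boundary mode); spans are tagged B-LIVER / I-LIVER.
hepatotoxicity
hepatic toxicity
hepatic failure
hepatic necrosis
hepatic injury
hepatic impairment
hepatic insufficiency
hepatocellular injury
hepatitis
liver failure
liver injury
liver disease
liver function
jaundice
hyperbilirubinemia
bilirubin
transaminase
aminotransferase
alkaline phosphatase
cholestat
ALT	word-boundary
AST	word-boundary
SGPT	word-boundary
SGOT	word-boundary
ALP	word-boundary
GGT	word-boundary
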