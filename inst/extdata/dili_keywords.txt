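#! name: dili_keywords
#! mode: substring-stem
#! case_insensitive: true
# DILI keyword list for the keyword baseline classifier: MedDRA-PT-style
# terms plus common labeling variants. Editable; labeling uses many
# non-standard variants, so extend freely.
hepatotoxicity
hepatic toxicity
hepatic failure
liver failure
hepatitis
hepatic necrosis
hepatocellular injury
liver injury
hepatic injury
jaundice
hyperbilirubinemia
transaminases increased
transaminase elevation
elevated transaminases
ALT increased	word-boundary
AST increased	word-boundary
hepatic impairment
hepatic function abnormal
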