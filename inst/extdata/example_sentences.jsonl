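{"text":"Hepatic toxicity including hepatic failure resulting in transplantation or death have been reported","dili_label":1,"liver_label":1}
{"text":"Rozerem should not be used by patients with severe hepatic impairment","dili_label":0,"liver_label":1}
{"text":"Treat all infections due to Group A beta-hemolytic streptococci for at least 10 days","dili_label":0,"liver_label":0}
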