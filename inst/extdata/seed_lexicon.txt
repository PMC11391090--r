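# Illustrative depression-related seed lexicon (synthetic, non-canonical).
# One term per line; extend with symptom terms and medication names.
抑郁
抑郁症
失眠
绝望
难过
哭
痛苦
自杀
药
孤独
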