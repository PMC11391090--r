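[泪]	流泪
[心]	爱心
[微笑]	微笑
[悲伤]	悲伤
[怒]	愤怒
[害羞]	害羞
[拜拜]	再见
[嘢呀]	开心
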