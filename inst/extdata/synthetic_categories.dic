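%
1	NegEmo
2	Anx
3	Sad
4	Anger
5	Swear
6	PosEmo
%
难过	1,3
痛苦	1
焦虑	1,2
害怕	2
哭*	1,3
愤怒	1,4
开心	6
快乐	6
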