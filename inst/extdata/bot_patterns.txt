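# seed list of platform-generated post markers; edit freely
生日提醒
会员等级
微博会员到期
自动回复
签到打卡
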