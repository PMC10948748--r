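{
  "self_reference": ["我", "我们", "我哋", "我的", "我嘅", "自己", "本人", "俺"],
  "negative_emotion": ["伤心", "难过", "悲伤", "哭", "痛苦", "失望", "烦",
                       "焦虑", "害怕", "孤独", "唔开心", "惨", "担心", "累",
                       "绝望", "内疚", "委屈", "愁"]
}
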