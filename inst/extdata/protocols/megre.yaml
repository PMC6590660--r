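# plain multi-echo spoiled gradient echo (FLASH) at the Ernst angle
name: ME-GRE
tr: 31.4      # ms
alpha: 12     # degrees
te: [3, 11.5, 20, 28.5]
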