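gauge,invitro_mean,invitro_sd,insilico_mean
1,-619.0,5.2,-543.65
2,-388.5,8.5,-508.12
3,460.5,2.9,411.58
4,36.5,12.7,39.997
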