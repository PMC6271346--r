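order,group,match,value
1,fungi,name,16:1ω5
2,bacteria,name,15:0
3,bacteria,category,iso_anteiso
4,bacteria,category,hydroxy
5,bacteria,category,cyclopropyl
6,bacteria,name,18:1ω8
7,autotrophs,category,C16_PUFA
8,autotrophs,category,C18_PUFA
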