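species,keystone_index
Oenocarpus bataua,7.32
Cecropia membranacea,6.36
Bursera inversa,5.90
Ficus davidsoni,5.41
Gustavia hexapetala,4.80
Brosimum alicastrum,4.51
Ficus sphenophylla,4.48
Brosimum guianense,4.31
Iriartea deltoidea,4.26
Astrocaryum chambira,3.98
Apeiba aspera,3.79
Pseudolmedia hirsuta,3.77
Brosimum utile,3.77
Ficus americana,3.72
Dialium guianense,3.58
Henriettella fissanthera,3.28
Ficus trigonata,3.16
Pourouma bicolor,3.07
Enterolobium schomburgkii,2.72
Ficus trigona,2.53
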