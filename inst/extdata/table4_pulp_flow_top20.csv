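species,pulp_biomass_g_ha_day
Pseudolmedia laevis,16938
Pseudolmedia hirsuta,11942
Pseudolmedia laevigata,8709
Spondias venulosa,3848
Oxandra mediocris,2660
Crepidospermum rhoifolium,2578
Talisia intermedia,2182
Socratea exorrhiza,1999
Alibertia cf. hadrantha,1705
Oenocarpus bataua,1674
Protium glabrescens,1208
Inga acreana,1174
Garcinia macrophylla,997
Gustavia hexapetala,966
Protium sagotianum,938
Coussapoa orthoneura,920
Spondias mombin,891
Castilla ulei,748
Cecropia membranacea,652
Brosimum lactescens,586
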