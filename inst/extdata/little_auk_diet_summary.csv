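taxon,gp2012_ra,gp2012_sd,gp2012_of,gp2014_ra,gp2014_sd,gp2014_of,shelf_ra,shelf_sd,shelf_of,break_ra,break_sd,break_of,ocean_ra,ocean_sd,ocean_of
C_hyperboreus,65.3,28.6,90,47.0,17.6,100,3.9,2.7,100,0.4,0.8,40,0.2,0.3,50
C_glacialis,15.5,9.2,95,34.1,12.8,100,6.3,3.1,100,1.8,3.2,80,0.6,0.8,75
C_finmarchicus,4.2,4.0,100,9.0,6.7,100,4.8,3.2,100,7.6,5.0,100,10.1,6.5,100
Calanus_CI_CIII,0.0,0.0,0,0.0,0.0,0,38.6,8.4,100,26.4,17.1,100,15.5,1.2,100
Small_copepods,0.0,0.0,0,0.0,0.0,0,16.1,9.5,100,36.6,15.7,100,42.4,4.4,100
Paraeuchaeta_spp,0.01,0.05,5,0.1,0.3,15,0.0,0.0,0,0.0,0.0,0,0.0,0.0,0
Oithona_spp,0.0,0.0,0,0.0,0.0,0,8.6,3.9,100,11.0,5.3,100,10.5,6.9,100
Apherusa_glacialis,8.7,26.4,45,0.1,0.3,20,0.0,0.0,0,0.0,0.0,0,0.0,0.0,0
Gammarus_spp,0.5,1.9,40,0.0,0.0,0,0.0,0.0,0,0.0,0.0,0,0.0,0.0,0
Onisimus_spp,0.3,0.7,40,0.0,0.0,0,0.0,0.0,0,0.0,0.0,0,0.0,0.0,0
Thysanoessa_spp,4.2,13.8,15,4.7,11.4,30,0.0,0.0,0,0.0,0.0,0,0.0,0.0,0
Themisto_spp,1.1,1.6,55,4.2,5.2,90,0.1,0.2,36,0.1,0.1,60,0.1,0.1,75
Decapod_larvae,0.01,0.03,5,0.1,0.3,10,0.0,0.0,0,0.0,0.0,0,0.0,0.0,0
Fish,0.03,0.1,10,0.2,0.3,30,0.0,0.0,0,0.0,0.0,0,0.0,0.0,0
Limacina_helicina,0.2,0.4,25,0.1,0.4,10,1.1,1.0,100,0.1,0.1,20,0.0,0.0,0
Nauplius_larvae,0.0,0.0,0,0.0,0.0,0,4.3,3.0,91,6.2,4.8,100,2.8,1.0,100
Tunicates,0.0,0.0,0,0.0,0.0,0,6.2,2.9,100,4.1,2.9,100,7.3,2.3,100
Echinodermata_larvae,0.0,0.0,0,0.0,0.0,0,5.9,6.4,91,0.6,0.3,100,0.3,0.3,75
Unknown,0.01,0.02,5,0.1,0.3,5,4.2,2.1,100,5.2,2.1,100,10.2,3.9,100
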