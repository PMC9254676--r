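location,species_id,F1,F2,F3,F4,F5,F6,U1,U2,U3,U4,U5,U6,U7,U3b,U4b
Port,swamp_wallaby,27.3,57.9,38.3,29.4,42.3,58.0,89.5,201.1,105.3,21.7,21.9,,,,
Port,eastern_grey_kangaroo,0.6,2.0,0.0,13.6,0,0,7.6,117.2,12.6,19.5,0,,,,
Port,red_necked_wallaby,0,0,0.0,3.8,0,0,2.2,76.6,2.8,0,0,,,,
Port,bandicoots,48.8,38.4,10.9,15.8,9.8,33.9,14.5,51.1,5.0,0,1.4,,,,
Port,red_necked_pademelon,48.8,174.9,18.6,9.0,9.8,19.3,139.0,7.6,1.6,0,0,,,,
Port,lace_monitor,1.9,10.4,4.4,0.8,3.3,4.8,36.2,65.2,79.7,99.7,23.3,,,,
Port,red_fox,0,0,0,0.8,1.6,1.2,12.3,35.0,86.4,0,0,,,,
Port,feral_cat,0,0,0,0,0,0,0,0.3,0,0,0,,,,
Port,dog_dingo,4.4,7.8,1.6,19.6,1.6,2.4,0,0.6,0.6,0,0,,,,
Port,brushtail_possums,31.1,118.3,6.0,3.8,1.6,6.0,2.5,1.6,0,0,19.2,,,,
Port,koala,1.9,3.3,1.1,0.8,0,0,0.9,0.3,2.2,0,0,,,,
Port,echidna,0.6,0.7,0.0,0.8,0,0,0.3,1.3,0,0,0,,,,
Port,fallow_deer,10.8,5.2,12.6,16.6,6.5,0,0,1.3,0,0,0,,,,
Grafton,swamp_wallaby,0,0,11.6,0,0.6,0.7,0,1.2,0,0,4.9,0.4,0.5,0,0
Grafton,eastern_grey_kangaroo,17.8,10.9,0,0,1.1,0,5.4,5.7,0.9,0,1.6,0,0,0,0
Grafton,red_necked_wallaby,21.9,35.6,0,2.6,5.0,1.4,11.1,14.2,0,0.4,15.0,8.3,10.3,2.9,1.2
Grafton,whiptail_wallaby,6.8,0,0,0,0,0,2.9,0,0,0,0,0,0,0,0
Grafton,bandicoots,22.6,25.3,59.5,10.6,24.9,14.4,7.0,9.3,1.9,0.4,0.4,22.5,0.5,21.0,0.4
Grafton,rufous_bettong,0,9.6,0.7,8.8,0.6,0,0,43.1,0,0,0,0,0.5,0,0
Grafton,lace_monitor,2.1,2.7,2.7,0,0,0.7,71.4,67.4,5.6,10.0,79.0,77.4,13.0,12.0,30.8
Grafton,red_fox,0,1.4,0,0,1.7,0.7,5.0,13.8,0,0.4,2.0,0.8,0.5,1.0,1.5
Grafton,feral_cat,2.1,0,1.4,0,0,0,7.8,0.8,0,0.9,0.4,1.7,0,0,0
Grafton,dog_dingo,0.7,6.2,1.4,0.9,6.1,0.7,1.7,2.8,0.5,1.8,8.1,6.2,1.2,1.0,3.1
Grafton,brushtail_possums,23.3,11.6,0,4.4,2.8,0,0,2.0,0,0,0,0,0,0,0
Grafton,echidna,8.9,3.4,1.4,0,0.6,0,16.5,2.0,0,0,0,0.8,0,0.4,0.4
Grafton,feral_horse,0,0,0,39.7,8.3,1.4,0,0,0,0,0,0,0,0,0
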