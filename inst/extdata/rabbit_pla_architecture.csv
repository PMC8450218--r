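animal_id,age_d,animal_mass_kg,ankle_angle_deg,knee_angle_deg,belly_length_mm,fascicle_length_mean_mm,fascicle_length_sd_mm,pennation_mean_deg,pennation_sd_deg,muscle_mass_g,pcsa_mm2,free_tendon_mm,aponeurosis_length_mm,aponeurosis_width_mm
R1,29,0.80,56.5,81.6,50.8,13.7,1.2,11.6,4.6,0.87,60.6,14.5,38.7,7.7
R2,29,0.60,62.9,83.4,50.4,13.8,1.2,10.1,3.6,0.71,49.1,14.2,37.0,7.3
R3,33,0.76,54.2,82.6,49.1,15.3,1.0,7.8,3.6,0.65,40.1,13.6,35.3,6.9
R4,64,2.30,71.5,88.4,78.6,16.2,1.5,10.8,5.2,3.28,192.1,22.6,62.6,14.6
R5,64,2.46,63.0,87.8,74.2,16.0,1.2,12.1,5.4,3.13,185.0,22.4,61.0,14.6
R6,78,2.00,60.6,89.8,77.5,16.6,1.4,9.3,5.1,2.37,134.9,7.6,62.0,12.4
R7,86,3.06,66.1,83.7,74.0,15.4,1.4,14.6,6.4,5.04,310.5,30.5,59.5,17.6
R8,106,5.00,60.3,87.1,87.2,19.0,1.3,13.2,5.6,7.00,350.3,26.3,68.0,20.2
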