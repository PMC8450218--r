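muscle,prediction_age_d,metric,error_pct
PLA,33,aponeurosis_length,5.3
PLA,33,aponeurosis_width,3.8
PLA,33,muscle_height,-5.9
PLA,33,muscle_mass,0.4
PLA,64,aponeurosis_length,-2.1
PLA,64,aponeurosis_width,0.4
PLA,64,muscle_height,8.5
PLA,64,muscle_mass,-3.6
PLA,78,aponeurosis_length,-4.8
PLA,78,aponeurosis_width,0.4
PLA,78,muscle_height,2.2
PLA,78,muscle_mass,4.7
PLA,86,aponeurosis_length,-4.4
PLA,86,aponeurosis_width,0.5
PLA,86,muscle_height,-7.2
PLA,86,muscle_mass,-17.3
PLA,106,aponeurosis_length,-2.5
PLA,106,aponeurosis_width,1.2
PLA,106,muscle_height,8.1
PLA,106,muscle_mass,-6.5
SOL,33,aponeurosis_length,15.8
SOL,33,aponeurosis_width,-15.9
SOL,33,muscle_height,-17.2
SOL,33,muscle_mass,-17.0
SOL,64,aponeurosis_length,-1.1
SOL,64,aponeurosis_width,-2.8
SOL,64,muscle_height,2.9
SOL,64,muscle_mass,1.3
SOL,78,aponeurosis_length,-3.5
SOL,78,aponeurosis_width,-1.9
SOL,78,muscle_height,5.1
SOL,78,muscle_mass,14.5
SOL,86,aponeurosis_length,-4.7
SOL,86,aponeurosis_width,-2.3
SOL,86,muscle_height,3.5
SOL,86,muscle_mass,14.3
SOL,106,aponeurosis_length,-5.0
SOL,106,aponeurosis_width,-1.2
SOL,106,muscle_height,4.5
SOL,106,muscle_mass,-12.3
SOL,109,aponeurosis_length,1.4
SOL,109,aponeurosis_width,-2.5
SOL,109,muscle_height,-3.6
SOL,109,muscle_mass,-11.8
GM,37,aponeurosis_length,13.8
GM,37,aponeurosis_width,10.5
GM,37,muscle_height,-12.7
GM,37,muscle_mass,-0.1
GM,50,aponeurosis_length,-13.7
GM,50,aponeurosis_width,-0.9
GM,50,muscle_height,19.0
GM,50,muscle_mass,-18.8
GM,70,aponeurosis_length,-1.7
GM,70,aponeurosis_width,0.3
GM,70,muscle_height,14.8
GM,70,muscle_mass,-3.8
GM,100,aponeurosis_length,-4.5
GM,100,aponeurosis_width,-2.1
GM,100,muscle_height,3.8
GM,100,muscle_mass,-9.1
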