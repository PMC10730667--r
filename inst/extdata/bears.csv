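,Abruzzo,Pyrenees,Kodiak,Captive-3,Captive-4,Captive-5,Grizzly,Polar-2,Black
Abruzzo,0.0,1.3,4.3,4.3,2.7,3.0,1.7,2.0,8.7
Pyrenees,1.3,0.0,4.3,4.3,2.3,3.0,1.7,2.0,8.0
Kodiak,4.3,4.3,0.0,0.7,5.0,1.3,2.7,3.0,10.0
Captive-3,4.3,4.3,0.7,0.0,5.0,1.3,2.7,3.0,10.0
Captive-4,2.7,2.3,5.0,5.0,0.0,3.7,2.3,2.7,10.0
Captive-5,3.0,3.0,1.3,1.3,3.7,0.0,2.0,2.3,8.7
Grizzly,1.7,1.7,2.7,2.7,2.3,2.0,0.0,0.3,9.0
Polar-2,2.0,2.0,3.0,3.0,2.7,2.3,0.3,0.0,9.4
Black,8.7,8.0,10.0,10.0,10.0,8.7,9.0,9.4,0.0
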