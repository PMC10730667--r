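9
Abruzzo
Pyrenees 1.3
Kodiak 4.3 4.3
Captive-3 4.3 4.3 0.7
Captive-4 2.7 2.3 5.0 5.0
Captive-5 3.0 3.0 1.3 1.3 3.7
Grizzly 1.7 1.7 2.7 2.7 2.3 2.0
Polar-2 2.0 2.0 3.0 3.0 2.7 2.3 0.3
Black 8.7 8.0 10.0 10.0 10.0 8.7 9.0 9.4
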