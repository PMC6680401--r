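locality,Norita,Venado,Amazcala,Zapote,Mompani,Zapote Viejo,Tlacote el Alto,Tlacote el Bajo
Norita,0,5.11,4.81,7.77,6.04,5.88,5.55,7.03
Venado,5.11,0,5.23,4.91,6.60,5.81,6.64,4.92
Amazcala,4.81,5.23,0,6.07,4.71,4.77,4.50,4.82
Zapote,7.77,4.91,6.07,0,5.70,4.79,6.43,2.60
Mompani,6.04,6.60,4.71,5.70,0,3.25,4.03,5.17
Zapote Viejo,5.88,5.81,4.77,4.79,3.25,0,2.34,3.68
Tlacote el Alto,5.55,6.64,4.50,6.43,4.03,2.34,0,4.97
Tlacote el Bajo,7.03,4.92,4.82,2.60,5.17,3.68,4.97,0
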