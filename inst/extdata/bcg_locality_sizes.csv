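locality,n
Norita,20
Zapote Viejo,38
Venado,11
Amazcala,15
Tlacote el Alto,22
Tlacote el Bajo,38
Zapote,59
Mompani,23
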