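variable,pc1,pc2,pc3,communality
HW,0.63,-0.07,-0.32,0.51
HL,0.65,-0.39,0.55,0.87
FL,0.61,-0.47,0.50,0.84
WH,0.70,0.31,0.25,0.66
CG,0.76,-0.01,-0.29,0.66
BL,0.63,0.37,-0.08,0.54
BW,0.44,-0.67,-0.41,0.81
CD,0.80,-0.18,0.00,0.67
SW,0.80,0.19,-0.14,0.69
RL,0.34,0.77,0.02,0.71
RW,0.75,0.08,-0.12,0.59
HAW,0.70,-0.20,-0.10,0.54
RH,0.70,0.32,0.34,0.71
CBP,0.78,0.03,-0.21,0.66
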