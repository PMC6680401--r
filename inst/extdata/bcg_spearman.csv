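var1,var2,rho,stars
FL,HL,0.87,***
FL,BW,0.24,***
FL,HAW,0.41,***
FL,CD,0.49,***
FL,HW,0.28,***
FL,CG,0.28,***
FL,CBP,0.36,***
FL,RW,0.26,***
FL,SW,0.32,***
FL,RH,0.35,***
FL,WH,0.31,***
FL,BL,0.23,***
FL,RL,0.00,
HL,BW,0.25,***
HL,HAW,0.39,***
HL,CD,0.52,***
HL,HW,0.27,***
HL,CG,0.31,***
HL,CBP,0.33,***
HL,RW,0.38,***
HL,SW,0.34,***
HL,RH,0.38,***
HL,WH,0.34,***
HL,BL,0.24,***
HL,RL,0.03,
BW,HAW,0.43,***
BW,CD,0.51,***
BW,HW,0.35,***
BW,CG,0.57,***
BW,CBP,0.38,***
BW,RW,0.40,***
BW,SW,0.32,**
BW,RH,0.15,
BW,WH,0.17,
BW,BL,0.20,
BW,RL,-0.11,***
HAW,CD,0.46,***
HAW,HW,0.39,***
HAW,CG,0.59,***
HAW,CBP,0.45,***
HAW,RW,0.58,***
HAW,SW,0.58,***
HAW,RH,0.32,***
HAW,WH,0.34,***
HAW,BL,0.42,***
HAW,RL,0.14,
CD,HW,0.48,***
CD,CG,0.65,***
CD,CBP,0.59,***
CD,RW,0.57,***
CD,SW,0.53,***
CD,RH,0.49,***
CD,WH,0.52,***
CD,BL,0.48,***
CD,RL,0.22,*
HW,CG,0.43,***
HW,CBP,0.57,***
HW,RW,0.44,***
HW,SW,0.42,***
HW,RH,0.32,***
HW,WH,0.43,***
HW,BL,0.35,***
HW,RL,0.18,
CG,CBP,0.55,***
CG,RW,0.58,***
CG,SW,0.64,***
CG,RH,0.44,***
CG,WH,0.44,***
CG,BL,0.49,***
CG,RL,0.32,***
CBP,RW,0.50,***
CBP,SW,0.56,***
CBP,RH,0.42,***
CBP,WH,0.47,***
CBP,BL,0.49,***
CBP,RL,0.32,***
RW,SW,0.59,***
RW,RH,0.49,***
RW,WH,0.44,***
RW,BL,0.48,***
RW,RL,0.40,***
SW,RH,0.48,***
SW,WH,0.46,***
SW,BL,0.55,***
SW,RL,0.40,***
RH,WH,0.78,***
RH,BL,0.43,***
RH,RL,0.44,***
WH,BL,0.49,***
WH,RL,0.40,***
BL,RL,0.48,***
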