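variable,mean,sd,cv,min,max
HW,11.56,0.98,8.50,9.50,18.00
HL,15.66,1.40,8.96,11.00,20.50
FL,12.74,1.45,11.38,9.00,19.50
WH,70.12,4.31,6.14,57.00,88.00
CG,84.07,7.36,8.76,56.00,106.00
BL,71.20,6.11,8.59,52.00,87.00
BW,21.88,5.10,23.32,15.60,41.00
CD,30.31,2.63,8.69,24.00,38.00
SW,16.86,1.53,9.07,13.00,24.00
RL,18.81,2.04,10.85,13.00,27.00
RW,15.61,1.40,8.95,12.50,21.00
HAW,17.17,1.79,10.43,12.20,23.00
RH,70.54,3.77,5.34,61.00,86.00
CBP,8.49,0.68,8.06,6.20,11.00
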