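operator,order,nsr_mean,nsr_sd,af_mean,af_sd,gamma_printed
mean,0,0.80,0.15,0.61,0.08,-0.15
mean,1,0.00,0.00,-0.04,0.02,0.99
mean,2,0.00,0.00,0.12,0.05,1.14
mean,3,0.00,0.00,-0.32,0.15,1.06
mean,4,0.00,0.01,0.75,0.40,0.83
mean,5,-0.01,0.02,-1.67,1.09,0.50
mean,6,0.01,0.06,3.69,3.28,0.10
mean,7,-0.02,0.20,-7.99,11.01,-0.29
mean,8,0.05,0.75,17.09,40.15,-0.58
mean,9,-0.10,2.38,-37.09,158.82,-0.77
mean,10,0.39,11.00,72.63,655.95,-0.89
sd,0,0.04,0.02,0.12,0.03,0.44
sd,1,0.03,0.02,0.27,0.07,1.82
sd,2,0.06,0.03,0.80,0.20,2.12
sd,3,0.14,0.10,2.58,0.75,1.87
sd,4,0.37,0.33,8.83,3.27,1.35
sd,5,1.01,1.19,31.77,15.13,0.89
sd,6,2.92,4.55,118.75,71.15,0.53
sd,7,8.91,18.03,457.43,335.68,0.27
sd,8,28.27,73.76,1806.84,1586.20,0.07
sd,9,93.13,309.85,7290.95,7516.51,-0.08
sd,10,317.51,1330.37,29965.71,35747.55,-0.20
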