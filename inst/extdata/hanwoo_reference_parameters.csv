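method,trait,sigma_a2,sigma_e2,sigma_p2,h2,h2_se,accuracy,accuracy_sd
PBLUP,CWT,603.79,1455.60,2059.39,0.29,0.03,0.53,0.02
PBLUP,EMA,34.29,85.70,119.99,0.29,0.03,0.53,0.02
PBLUP,BFT,4.07,13.74,17.82,0.23,0.03,0.52,0.02
PBLUP,MS,1.25,1.98,3.23,0.39,0.04,0.54,0.02
ssGBLUP,CWT,859.69,1143.70,2003.39,0.43,0.01,0.73,0.04
ssGBLUP,EMA,43.99,74.43,118.42,0.37,0.01,0.71,0.04
ssGBLUP,BFT,6.39,11.53,17.92,0.36,0.01,0.70,0.04
ssGBLUP,MS,1.51,1.70,3.21,0.47,0.01,0.74,0.04
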