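marker,timepoint,mean_estimate,mean_low,mean_high,mean_p,sd_estimate,sd_low,sd_high,sd_p
COMP,t1,29.3,23.8,34.8,0.0005,12.3,8.7,17.5,0.0005
COMP,t2,5.5,2.7,8.4,0.0005,5.9,3.8,9.0,0.0005
COMP,t3,-0.4,-3.1,2.3,0.783,4.9,2.8,8.5,0.023
MMP-3,t1,26.7,22.2,31.2,0.0005,9.5,6.4,14.1,0.0005
MMP-3,t2,13.1,9.8,16.5,0.0005,6.9,4.5,10.6,0.001
MMP-3,t3,4.2,1.6,6.8,0.002,5.0,3.0,8.3,0.010
MMP-9,t1,1.1,-3.1,5.3,0.597,0.0,0.0,0.2,1.000
MMP-9,t2,-0.1,-5.1,5.0,0.977,9.0,5.0,16.2,0.039
MMP-9,t3,2.7,-5.7,11.1,0.525,16.3,10.1,26.4,0.006
PRG-4,t1,2.1,-4.6,8.7,0.544,6.2,0.6,65.7,0.666
PRG-4,t2,-6.9,-12.8,Inf,0.023,0.0,0.0,Inf,1.000
PRG-4,t3,0.5,-8.9,9.9,0.919,0.0,0.0,Inf,1.000
ADAMTS-4,t1,3.2,0.7,5.8,0.014,0.0,0.0,Inf,1.000
ADAMTS-4,t2,-0.7,-4.8,3.3,0.722,0.0,0.0,Inf,1.000
ADAMTS-4,t3,1.0,-2.4,4.5,0.563,0.0,0.0,Inf,1.000
IL-6,t1,6.1,3.0,9.2,0.0005,4.6,1.9,11.3,0.219
IL-6,t2,9.5,4.0,15.0,0.0005,10.9,6.9,17.4,0.003
IL-6,t3,21.3,12.3,30.2,0.0005,18.7,12.3,28.4,0.0005
C2C,t1,1.6,-2.2,5.5,0.406,4.7,1.2,18.5,0.446
C2C,t2,3.6,-0.5,7.7,0.086,0.0,0.0,Inf,1.000
C2C,t3,1.3,-3.9,6.5,0.617,0.0,0.0,Inf,1.000
CPII,t1,4.9,0.4,9.3,0.032,0.0,0.0,Inf,1.000
CPII,t2,3.3,-2.9,9.4,0.299,0.0,0.0,Inf,1.000
CPII,t3,5.5,-2.5,13.5,0.179,0.0,0.0,Inf,1.000
CPII/C2C,t1,3.7,-0.1,7.6,0.058,0.0,0.0,Inf,1.000
CPII/C2C,t2,1.5,-3.9,6.9,0.583,0.0,0.0,Inf,1.000
CPII/C2C,t3,4.4,-3.0,11.9,0.239,0.0,0.0,Inf,1.000
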