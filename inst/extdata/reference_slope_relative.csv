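marker,timepoint,mean_estimate,mean_low,mean_high,mean_p,sd_estimate,sd_low,sd_high,sd_p
COMP,t1,4.9,1.7,8.1,0.003,4.0,1.7,9.1,0.027
COMP,t2,2.1,-0.2,4.4,0.074,3.9,1.9,8.1,0.075
COMP,t3,0.6,-1.9,3.1,0.645,3.7,1.4,9.7,0.274
MMP-3,t1,8.0,4.9,11.2,0.0005,4.1,1.8,8.9,0.022
MMP-3,t2,5.7,3.2,8.2,0.0005,2.4,0.2,31.9,0.161
MMP-3,t3,4.2,1.9,6.5,0.0005,3.3,1.2,9.5,0.041
MMP-9,t2,-2.4,-7.1,2.4,0.329,6.1,2.6,14.3,0.042
MMP-9,t3,-0.5,-7.7,6.7,0.894,10.7,4.1,28.2,0.122
ADAMTS-4,t1,1.0,-3.2,5.2,0.630,8.4,5.3,13.4,0.008
IL-6,t1,-2.3,-5.7,1.1,0.189,4.9,2.3,10.7,0.033
IL-6,t2,1.1,-3.1,5.3,0.607,2.7,0.4,17.9,0.296
IL-6,t3,0.8,-6.5,8.1,0.826,12.6,6.4,24.8,0.108
CPII,t1,2.0,-5.2,9.2,0.582,14.0,8.6,22.8,0.010
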