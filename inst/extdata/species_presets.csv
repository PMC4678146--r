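species,mu,gamma,theta,M,p,n_theta,time_unit
human,0.5,10,1e9,1e10,1e-6,4,year
mouse,1,1e-4,2.5e6,1e10,1e-6,4,month
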