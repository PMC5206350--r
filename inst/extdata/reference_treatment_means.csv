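parameter,treatment,mean,se,n
n_visibly_growing,N1V1,3.6,0.1,16
n_visibly_growing,N1V2,3.8,0.1,16
n_visibly_growing,N2V1,4.2,0.1,16
n_visibly_growing,N2V2,3.8,0.1,16
n_phytomers,N1V1,13.4,0.2,16
n_phytomers,N1V2,13.3,0.2,16
n_phytomers,N2V1,14.5,0.2,16
n_phytomers,N2V2,13.7,0.2,16
phyllochron,N1V1,2.4,0.1,16
phyllochron,N1V2,2.4,0.0,16
phyllochron,N2V1,2.1,0.0,16
phyllochron,N2V2,2.4,0.1,16
visible_growth_duration,N1V1,11.0,0.5,16
visible_growth_duration,N1V2,11.8,0.2,16
visible_growth_duration,N2V1,10.6,0.2,16
visible_growth_duration,N2V2,10.6,0.3,16
n_tillers,N1V1,19.7,1.8,16
n_tillers,N1V2,17.6,1.0,16
n_tillers,N2V1,24.0,1.1,16
n_tillers,N2V2,21.7,1.6,16
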