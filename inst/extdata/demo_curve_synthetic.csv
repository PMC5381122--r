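# cytostretch strain-force curve
# seed: 42
force_N,strain_mean,strain_se,n
5e-10,0.087437391,0.00938673389,10
1e-09,0.139744646,0.0128633638,10
1.6e-09,0.193453305,0.0173073128,10
2.2e-09,0.260013627,0.0211027781,10
2.9e-09,0.301690107,0.0246007981,10
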