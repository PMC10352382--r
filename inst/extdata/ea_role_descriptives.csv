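role,n,n_female,n_male,pairs,age_min,age_max,mean_ea,sd_ea
mz_twin,1020,610,410,498,22,27,14.7,2.94
dz_twin,896,511,385,439,22,27,14.4,3.05
sibling,215,116,99,0,21,30,14.8,3.09
mother,906,906,0,0,41,66,12.6,2.81
father,536,0,536,0,44,79,13.5,3.23
total,3573,2143,1430,937,21,79,13.9,3.10
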