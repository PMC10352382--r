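dyad,r,n_pairs
mz_twins,0.769,498
dz_twins,0.595,439
sibling_twin,0.453,212
mother_twin,0.406,884
mother_sibling,0.497,201
father_twin,0.418,525
father_sibling,0.388,132
parents,0.597,482
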