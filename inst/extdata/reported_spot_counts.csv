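category,condition,n_spots
fibroblast_dominant,day0,136
fibroblast_dominant,day19,521
immune_rich,day0,169
immune_rich,day19,863
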