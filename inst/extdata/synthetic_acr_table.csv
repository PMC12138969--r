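"taxon_class","acr","acr_min","acr_max","source_id"
"Insecta",22.6,5,150,"synthetic"
"Malacostraca",12,6,30,"synthetic"
"Branchiopoda",10,8,15,"synthetic"
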