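"species","class","duration_days","endpoint","effect_concentration_ugL","source_id"
"reference Insecta","Insecta","                 1","LC50","416.72589193265389","synthetic"
"reference Insecta","Insecta","                 2","LC50"," 118.1812615171648","synthetic"
"reference Insecta","Insecta","                 4","LC50","28.788526033062592","synthetic"
"reference Insecta","Insecta","                 7","LC50","12.416583460137664","synthetic"
"reference Insecta","Insecta","                14","LC50","3.2131082236955533","synthetic"
"reference Insecta","Insecta","                21","LC50","1.4688756531581431","synthetic"
"reference Insecta","Insecta","                28","LC50","0.75429758617083686","synthetic"
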