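"species","class","duration_days","endpoint","effect_concentration_ugL","source_id"
"reference Branchiopoda","Branchiopoda","                 1","LC50","387.62995318915506","synthetic"
"reference Branchiopoda","Branchiopoda","                 2","LC50","32.369761434748618","synthetic"
"reference Branchiopoda","Branchiopoda","                 4","LC50","1.8960238746730715","synthetic"
"reference Branchiopoda","Branchiopoda","                 7","LC50","0.18872228829207727","synthetic"
"reference Branchiopoda","Branchiopoda","                14","LC50","0.013110018760399404","synthetic"
"reference Branchiopoda","Branchiopoda","                21","LC50","0.0026012513102985674","synthetic"
"reference Branchiopoda","Branchiopoda","                28","LC50","0.0009629289513602492","synthetic"
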