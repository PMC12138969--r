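"species","class","phylum","medium","endpoint","effect_type","concentration","conc_unit","duration","duration_unit","purity_pct","quality_pct","source_id"
"Synthspecies 001","Insecta","Arthropoda","freshwater","LC50","acute","124.23302047227601","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 002","Insecta","Arthropoda","freshwater","LC50","acute","1138.9861631367116","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 003","Insecta","Arthropoda","freshwater","LC50","acute","13.851536912569994","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 004","Insecta","Arthropoda","freshwater","LC50","acute","25.350098705350646","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 005","Insecta","Arthropoda","freshwater","LC50","acute","217.59579601087472","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 006","Insecta","Arthropoda","freshwater","LC50","acute","39.308398536714442","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 007","Insecta","Arthropoda","freshwater","LC50","acute"," 9.630196811914967","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 008","Insecta","Arthropoda","freshwater","LC50","acute","195.57707836129367","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 009","Insecta","Arthropoda","freshwater","LC50","acute","25651.155200410238","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 010","Insecta","Arthropoda","freshwater","LC50","acute","499.37117431698567","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 011","Insecta","Arthropoda","freshwater","LC50","acute"," 928.1388786345475","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 012","Insecta","Arthropoda","freshwater","LC50","acute","89.084440407382218","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 013","Insecta","Arthropoda","freshwater","LC50","acute","567.16256437079983","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 014","Insecta","Arthropoda","freshwater","LC50","acute","861.75800373118193","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 015","Insecta","Arthropoda","freshwater","LC50","acute","17137.054864084934","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 016","Insecta","Arthropoda","freshwater","LC50","acute","77442.147915332083","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 017","Malacostraca","Arthropoda","freshwater","LC50","acute","633.76563008432333","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 018","Malacostraca","Arthropoda","freshwater","LC50","acute","36.475663812026355","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 019","Malacostraca","Arthropoda","freshwater","LC50","acute","16880.353055110143","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 020","Malacostraca","Arthropoda","freshwater","LC50","acute","1418.5167170962468","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 021","Malacostraca","Arthropoda","freshwater","LC50","acute","14.013953252758247","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 022","Malacostraca","Arthropoda","freshwater","LC50","acute","59.582406025048009","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 023","Malacostraca","Arthropoda","freshwater","LC50","acute","12255.690461986451","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 024","Malacostraca","Arthropoda","freshwater","LC50","acute","58.213336119280761","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 025","Malacostraca","Arthropoda","freshwater","LC50","acute"," 1091.930821124105","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 026","Malacostraca","Arthropoda","freshwater","LC50","acute","14332.044453502122","ug/L","                 4","days","                99","                90","synthetic-community"
"Synthspecies 027","Branchiopoda","Arthropoda","freshwater","LC50","acute","554.59538727995835","ug/L","                 2","days","                99","                90","synthetic-community"
"Synthspecies 028","Branchiopoda","Arthropoda","freshwater","LC50","acute","310.60438279099435","ug/L","                 2","days","                99","                90","synthetic-community"
"Synthspecies 029","Branchiopoda","Arthropoda","freshwater","LC50","acute","47.092620326981361","ug/L","                 2","days","                99","                90","synthetic-community"
"Synthspecies 030","Branchiopoda","Arthropoda","freshwater","LC50","acute"," 1552.560977602991","ug/L","                 2","days","                99","                90","synthetic-community"
"Synthspecies 031","Branchiopoda","Arthropoda","freshwater","LC50","acute","39.698985163534566","ug/L","                 2","days","                99","                90","synthetic-community"
"Synthspecies 032","Branchiopoda","Arthropoda","freshwater","LC50","acute","1407.0790808913785","ug/L","                 2","days","                99","                90","synthetic-community"
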