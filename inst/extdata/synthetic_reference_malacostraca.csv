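"species","class","duration_days","endpoint","effect_concentration_ugL","source_id"
"reference Malacostraca","Malacostraca","                 1","LC50","376.63971667065897","synthetic"
"reference Malacostraca","Malacostraca","                 2","LC50","240.18422447940625","synthetic"
"reference Malacostraca","Malacostraca","                 4","LC50","138.91502217364888","synthetic"
"reference Malacostraca","Malacostraca","                 7","LC50","105.69773358189003","synthetic"
"reference Malacostraca","Malacostraca","                14","LC50","51.439180831951752","synthetic"
"reference Malacostraca","Malacostraca","                21","LC50","42.008041969588596","synthetic"
"reference Malacostraca","Malacostraca","                28","LC50","49.080360919609298","synthetic"
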