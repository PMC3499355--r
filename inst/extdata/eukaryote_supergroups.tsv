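genome_id	supergroup
Deuterostomia	Opisthokonta
Neoptera	Opisthokonta
Protostomia_other	Opisthokonta
Cnidaria	Opisthokonta
Placozoa	Opisthokonta
Porifera	Opisthokonta
Choanoflagellata	Opisthokonta
Capsaspora	Opisthokonta
Ascomycota	Opisthokonta
Basidiomycota	Opisthokonta
Fungi_other	Opisthokonta
Thecamonas	Opisthokonta
Dictyostelium	Amoebozoa
Amoebozoa_other	Amoebozoa
Micromonas	Archaeplastida
Chlorophyta_other	Archaeplastida
Embryophyta	Archaeplastida
Rhodophyta	Archaeplastida
Alveolata	Chromalveolata
Stramenopiles	Chromalveolata
Excavata	Excavata
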