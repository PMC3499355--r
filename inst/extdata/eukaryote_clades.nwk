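(((((((Deuterostomia,(Neoptera,Protostomia_other)Protostomia)Bilateria,Cnidaria,Placozoa,Porifera)Metazoa,Choanoflagellata,Capsaspora)Holozoa,((Ascomycota,Basidiomycota)Dikarya,Fungi_other)Fungi)Opisthokonta,Thecamonas)Opisthokonta_plus,(Dictyostelium,Amoebozoa_other)Amoebozoa)Unikonta,((((Micromonas,Chlorophyta_other)Chlorophyta,Embryophyta)Viridiplantae,Rhodophyta)Archaeplastida,(Alveolata,Stramenopiles)Chromalveolata,Excavata)Bikonta)Eukaryota;
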