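category,rank
seeds,1
flowers,1
leaves,1
fruit,1
grass blades,1
plant stems,1
pollen,1
Isoptera,2
Pentatomidae,2
Orthoptera,2
Hemiptera,2
Acrididae,2
Lepidoptera larvae,2
Lepidoptera,2
Cicadidae,2
Cicadellidae,2
Fulgoridae,2
Aphididae,2
Coccoidea,2
Curculionidae,2
Chrysomelidae,2
Scarabaeidae,2
Tenebrionidae,2
Phasmatodea,2
Psyllidae,2
Thysanoptera,2
Embioptera,2
Collembola,2
Isopoda,2
Lygaeidae,2
Coleoptera,2.5
Coleoptera larvae,2.5
insect larvae,2.5
insect eggs,2.5
Blattodea,2.5
Gryllidae,2.5
Tettigoniidae,2.5
Diptera,2.5
Diptera larvae,2.5
Hymenoptera,2.5
Formicidae,3
Gryllacrididae,3
Dermaptera,3
Acarina,3
Opiliones,3
Araneae,3.5
Chilopoda,3.5
Scorpiones,3.5
Pseudoscorpiones,3.5
Vespidae,3.5
Reduviidae,3.5
Asilidae,3.5
Carabidae,3.5
Neuroptera,3.5
Arachnida,3.5
Mantodea,4
Solifugae,4
Myrmeleontidae,4
Odonata,4
Diplopoda,2
vertebrates,5
Scincidae,5
Gekkonidae,5
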