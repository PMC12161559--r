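taxon,group
Amphipoda:Americorophium,Amphipoda
Amphipoda:other,Amphipoda
Diptera:Chironomidae,Diptera
Diptera:other,Diptera
Cladocera:Daphnia,Cladocera
Hemiptera:Corixidae,Hemiptera
Trichoptera,Trichoptera
Hymenoptera,Hymenoptera
other,Other
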