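group,ranch,control
Pelagic fishes,2.12,0.48
Large and medium demersal fishes,0.23,0.24
Sparids,0.38,0.027
Leiognathidae,0.9,0.26
Small demersal fishes,0.62,0.16
Scorpaenidae,0.62,0.11
Gobiidae,0.87,0.098
Mantis shrimps,0.34,0.12
Large crabs,0.85,0.40
Other crabs,0.86,0.135
Metapenaeopsis barbata,1.6,0.40
Other shrimps,3.1,0.95
Cephalopods,0.34,0.12
Gastropods,1.82,0.36
Barnacles,90,
Oysters,96,
Mussels,163,
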