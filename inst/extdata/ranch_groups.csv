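name,role,TL_published,B,PB,QB,EE_published,Ui
Pelagic fishes,consumer,2.70,0.11,0.60,16.29,0.76,0.20
Large and medium demersal fishes,consumer,3.42,0.18,1.16,12.82,0.77,0.20
Sparids,consumer,3.46,0.33,0.95,14.43,0.19,0.20
Leiognathidae,consumer,2.86,0.24,2.40,14.12,0.50,0.20
Small demersal fishes,consumer,3.22,0.18,1.76,13.60,0.72,0.20
Scorpaenidae,consumer,3.27,0.02,0.97,4.00,0.25,0.20
Gobiidae,consumer,3.22,0.07,2.32,12.96,0.86,0.20
Mantis shrimps,consumer,3.08,0.12,5.98,30.81,0.18,0.20
Large crabs,consumer,2.89,0.30,5.49,26.79,0.92,0.20
Other crabs,consumer,3.13,0.30,6.82,30.35,0.75,0.20
Metapenaeopsis barbata,consumer,2.33,0.52,7.89,27.61,0.31,0.20
Other shrimps,consumer,2.37,1.50,6.68,23.92,0.63,0.20
Cephalopods,consumer,3.28,0.07,3.81,14.83,0.80,0.20
Sea urchins,consumer,2.10,11.43,6.38,23.60,0.01,0.20
Gastropods,consumer,2.46,0.88,5.75,23.83,0.63,0.20
Barnacles,consumer,2.02,30.00,6.15,27.19,0.01,0.20
Oysters,consumer,2.02,21.76,4.61,20.93,0.07,0.40
Mussels,consumer,2.02,80.40,5.06,19.34,0.05,0.40
Other bivalves,consumer,2.02,1.58,6.20,23.46,0.74,0.40
Other benthos,consumer,2.34,0.93,6.10,21.95,0.61,0.35
Zooplankton,consumer,2.00,4.17,32.54,192.47,0.73,0.40
Phytoplankton,producer,1.00,27.74,113.82,,0.68,
Detritus,detritus,1.00,32.55,,,0.55,
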