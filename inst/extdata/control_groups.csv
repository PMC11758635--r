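name,role,TL_published,B,PB,QB,EE_published,Ui
Pelagic fishes,consumer,2.70,0.06,0.60,16.29,0.73,0.20
Large and medium demersal fishes,consumer,3.35,0.18,1.30,15.18,0.78,0.20
Sparids,consumer,3.63,0.01,0.73,15.87,0.69,0.20
Leiognathidae,consumer,2.84,0.18,2.75,17.81,0.01,0.20
Small demersal fishes,consumer,3.16,0.12,1.83,12.75,0.61,0.20
Scorpaenidae,consumer,3.30,0.00,0.97,4.00,0.16,0.20
Gobiidae,consumer,3.16,0.07,2.30,13.92,0.41,0.20
Mantis shrimps,consumer,3.01,0.13,5.18,31.68,0.13,0.20
Large crabs,consumer,2.84,0.33,4.67,24.38,0.34,0.20
Other crabs,consumer,3.09,0.11,4.84,24.90,0.92,0.20
Metapenaeopsis barbata,consumer,2.31,0.06,7.40,28.04,0.91,0.20
Other shrimps,consumer,2.37,0.58,6.77,25.85,0.96,0.20
Cephalopods,consumer,3.25,0.07,4.58,15.82,0.36,0.20
Gastropods,consumer,2.42,0.26,5.70,23.80,0.65,0.20
Bivalves,consumer,2.01,2.86,5.65,23.77,0.95,0.40
Other benthos,consumer,2.08,0.11,6.10,21.95,0.89,0.35
Zooplankton,consumer,2.00,3.13,32.39,192.29,0.07,0.40
Phytoplankton,producer,1.00,24.64,113.82,,0.16,
Detritus,detritus,1.00,41.03,,,0.09,
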