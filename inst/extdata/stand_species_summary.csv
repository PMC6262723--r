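species,growth_form,density_2002,ba_2002,density_2015,ba_2015,max_dbh,mortality,recruitment,ingrowth,pooled
Abies firma,EC,98,7.44,82,7.73,108.4,1.956,0.585,1.425,FALSE
Chamaecyparis obtusa,EC,72,6.88,70,6.69,105.2,0.669,0.453,1.279,FALSE
Torreya nucifera,EC,34,2.33,30,2.76,109.1,1.494,0.531,1.341,FALSE
Tsuga sieboldii,EC,18,2.24,20,2.44,103.3,0.906,1.716,0.994,FALSE
Sciadopitys verticillata,EC,32,1.94,30,2.45,114.2,0.496,0.000,1.814,FALSE
Others EC,EC,8,0.005,6,0.005,4.0,5.332,3.119,1.475,TRUE
Fagus japonica,DH,150,3.97,100,3.67,61.7,3.433,0.314,2.198,FALSE
Carpinus japonica,DH,30,1.20,16,1.16,46.0,5.863,1.027,2.758,FALSE
Carpinus laxiflora,DH,28,1.18,24,1.44,53.0,1.186,0.000,1.553,FALSE
Acer sieboldianum,DH,32,0.77,30,0.89,39.9,0.496,0.000,1.056,FALSE
Sapium japonicum,DH,156,0.66,132,0.86,19.4,1.766,0.481,2.623,FALSE
Callicarpa japonica,DH,42,0.04,16,0.05,12.1,14.969,7.545,1.993,FALSE
Others DH,DH,216,2.25,168,3.18,NA,4.025,2.092,2.848,TRUE
Illicium anisatum,EH,354,1.75,410,1.71,22.2,2.084,3.213,1.592,FALSE
Quercus myrsinifolia,EH,98,0.61,92,0.89,37.7,1.005,0.519,2.987,FALSE
Eurya japonica,EH,230,0.56,288,0.84,14.5,0.412,2.248,2.940,FALSE
Pieris japonica,EH,110,0.48,70,0.35,20.0,3.700,0.223,1.152,FALSE
Quercus salicina,EH,38,0.15,34,0.20,16.9,1.322,0.466,2.520,FALSE
Others EH,EH,58,0.49,58,0.61,NA,1.783,1.783,2.896,TRUE
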