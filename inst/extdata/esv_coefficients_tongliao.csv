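category,service,farmland,forest,grassland,water,built-up,unused
Provisioning services,Food production,822.500,271.425,353.675,435.925,0,16.450
Provisioning services,Raw material,320.775,2451.050,296.100,287.875,0,32.900
Regulating services,Gas regulation,592.200,3553.200,1233.750,419.475,0,49.350
Regulating services,Climate regulation,797.825,3347.575,1283.100,1694.350,0,106.925
Regulating services,Waste treatment,1209.075,3306.450,1842.400,337.225,0,139.825
Supporting services,Water conservation,633.325,3364.025,1250.200,15438.325,0,57.575
Supporting services,Soil fertility maintenance,1143.275,1414.700,1085.700,12214.125,0,213.850
Supporting services,Biodiversity protection,838.950,3709.475,1538.075,2821.175,0,329.000
Cultural services,Recreation and culture,139.825,1710.800,715.575,3651.900,0,197.400
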