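class,y2000,y2005,y2010,y2015,y2020,y2035
farmland,17508.93,17834.52,17877.61,17932.10,17850.11,17753.30
forest,4659.98,4654.55,4643.53,4641.51,4599.44,4551.23
grassland,25582.02,25424.99,25298.35,25157.32,25201.94,25248.91
water,1256.17,1134.02,1132.01,1121.97,1132.56,1143.88
built-up,1304.49,1328.56,1344.28,1494.51,1525.05,1545.27
unused,8476.59,8411.54,8492.40,8440.77,8479.08,8545.59
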