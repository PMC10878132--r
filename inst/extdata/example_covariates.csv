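province,year,garbage_disposal,domestic_sewage,waste_incineration
Guangdong,2013,2605,745,410
Guangdong,2016,2820,812,655
Guangdong,2019,3012,880,1105
Zhejiang,2013,1105,520,388
Zhejiang,2016,1230,585,540
Zhejiang,2019,1408,640,830
Fujian,2013,702,310,150
Fujian,2016,805,355,260
Fujian,2019,930,402,470
Beijing,2013,671,380,160
Beijing,2016,805,420,330
Beijing,2019,1011,452,602
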