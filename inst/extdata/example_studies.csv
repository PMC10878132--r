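study_id,matrix,province,year_start,year_end,sex,age_min,age_max,n,summary_kind,s1,s2,s3,unit,lod
S01,urine,Guangdong,2018,2019,mixed,19,44,120,GM_GSD,2.9,2.1,,ng/mL,0.3
S02,urine,Zhejiang,2012,2013,female,19,44,260,MEDIAN_IQR,1.1,2.3,4.6,ng/mL,0.3
S03,urine,Fujian,2015,2016,male,19,44,85,MEDIAN_RANGE,0.2,2.0,9.5,ug/L,0.3
S04,serum,Jiangsu,2016,2019,mixed,0,6,48,AM_SD,7.9,5.2,,ng/mL,0.5
S05,serum,Shandong,2008,2010,mixed,19,79,300,MEAN_CI,2.4,2.1,2.7,ng/mL,0.5
S06,urine,Beijing,2009,2011,mixed,7,18,150,GM_GSD,1.85,1.9,,ng/mL,0.3
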