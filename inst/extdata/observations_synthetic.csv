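site_id,year,date,compound,f14c,sigma_f14c,delta14c,latitude,longitude,coord_flag,uncertainty_flag,catchment_area_km2,water_type,lithology_raw,biome_raw
AMZ-01,2005,2005-07-02,DIC,0.914,0.004,,-3.1,-60.0,1,1,4680000,river,SM,1
AMZ-01,2005,2005-07-02,CO2,0.934,0.005,,-3.1,-60.0,1,1,4680000,river,SM,1
MOOR-1,2012,2012-05-20,DIC,1.002,0.003,,54.7,-2.4,1,1,8.5,stream,SS,8
MOOR-1,2012,2012-05-20,CO2,0.982,0.003,,54.7,-2.4,1,1,8.5,stream,SS,8
TAIW-3,2016,2016-03-11,DIC,,0.004,-112.4,23.5,121.0,2,1,430,river,MT,3
ICEL-2,2009,2009-08-30,CO2,1.054,0.006,,64.8,-18.2,1,2,95,stream,VB,6
SIB-44,2018,,CH4,0.612,0.010,,66.9,93.2,3,2,18300,river,SU,6
PER-07,2014,2014-06-15,DIC,0.968,0.004,,-12.1,-71.3,1,1,5200,river,SC,1
REP-9,2015,2015-01-10,DIC,0.90,0.005,,57.1,-4.5,1,1,6.2,stream,PB,5
REP-9,2015,2015-03-14,DIC,0.92,0.005,,57.1,-4.5,1,1,6.2,stream,PB,5
REP-9,2015,2015-05-18,DIC,0.94,0.005,,57.1,-4.5,1,1,6.2,stream,PB,5
REP-9,2015,2015-07-22,DIC,0.96,0.005,,57.1,-4.5,1,1,6.2,stream,PB,5
REP-9,2015,2015-09-25,DIC,0.98,0.005,,57.1,-4.5,1,1,6.2,stream,PB,5
BAD-1,2010,2010-04-01,N2O,0.95,0.004,,50.0,8.0,1,1,120,river,SS,4
BAD-2,1930,1930-04-01,DIC,0.95,0.004,,50.0,8.0,1,1,120,river,SS,4
BAD-3,2010,2010-04-01,DIC,-0.2,0.004,,50.0,8.0,1,1,120,river,SS,4
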