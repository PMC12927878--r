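survey,quantity,value,unit
jds2,tt_cum_days,33.7,days
jds3,tt_cum_days,49.7,days
jds2,journey_days,33.7,days
jds3,journey_days,53.6,days
jds2,cd_daily_median,0.124,1/day
jds3,cd_daily_median,0.121,1/day
jds2,tcc_median,1.71e9,cells/l
jds3,tcc_median,13.9e9,cells/l
jds2,bsp_median,0.32,ugC/l/h
jds3,bsp_median,1.15,ugC/l/h
jds2,bsp_c_median,0.19,fgC/cell/h
jds3,bsp_c_median,0.09,fgC/cell/h
jds2,cp_tot,9.21e9,cells/l
jds3,cp_tot,95.9e9,cells/l
jds2,bsp_c_slope,-422e-21,gC/cell/h per travel-hour
jds3,bsp_c_slope,-119e-21,gC/cell/h per travel-hour
jds2,tcc_slope,0.93e6,cells/l per travel-hour
jds3,tcc_slope,9.52e6,cells/l per travel-hour
jds2_fl,richness_slope,-0.145,ASV/h
jds2_pa,richness_slope,-0.181,ASV/h
jds3,richness_slope,-0.063,ASV/h
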