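analyte,wavelength_nm,slope,intercept,r_squared,range_low,range_high,n_points
cholesterol,205,206.39,-1.93,1.0000,1000,1200,8
stigmasterol,205,1704.6,16.13,0.9997,6.43,77.21,8
7-hydroxycholesterol,205,316.9,3.13,0.9998,39.47,473.70,8
7-ketocholesterol,240,1094.3,-0.33,1.0000,8.13,97.57,8
4-cholesten-3-one,240,1120.8,1.10,1.0000,5.05,60.67,8
7-dehydrocholesterol,280,620.05,-0.42,0.9999,2.44,29.32,8
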