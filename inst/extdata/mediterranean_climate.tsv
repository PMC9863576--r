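country	variable	period	value
Albania	Tmax	SA	11.8
Albania	Tmin	SA	3.3
Albania	Tmean	SA	7.6
Albania	Rh	SA	75.7
Albania	Sunshine	SA	2.8
Albania	Rad	SA	7.1
Albania	ET0	SA	6
Albania	Rain	SA	663.4
Albania	Tmax	AM	23.1
Albania	Tmin	AM	11.6
Albania	Tmean	AM	17.4
Albania	Rh	AM	63.1
Albania	Sunshine	AM	7.2
Albania	Rad	AM	19.5
Albania	ET0	AM	11.2
Albania	Rain	AM	192.2
Algeria	Tmax	SA	16.1
Algeria	Tmin	SA	6.1
Algeria	Tmean	SA	11.1
Algeria	Rh	SA	75.4
Algeria	Sunshine	SA	5.4
Algeria	Rad	SA	11
Algeria	ET0	SA	200
Algeria	Rain	SA	193.4
Algeria	Tmax	AM	26.1
Algeria	Tmin	AM	13.6
Algeria	Tmean	AM	19.9
Algeria	Rh	AM	60.7
Algeria	Sunshine	AM	8.6
Algeria	Rad	AM	22.1
Algeria	ET0	AM	385.2
Algeria	Rain	AM	78.2
Bosnia & Herzegovina	Tmax	SA	8.8
Bosnia & Herzegovina	Tmin	SA	0.6
Bosnia & Herzegovina	Tmean	SA	4.7
Bosnia & Herzegovina	Rh	SA	76
Bosnia & Herzegovina	Sunshine	SA	1.8
Bosnia & Herzegovina	Rad	SA	5.7
Bosnia & Herzegovina	ET0	SA	4.9
Bosnia & Herzegovina	Rain	SA	554.5
Bosnia & Herzegovina	Tmax	AM	21.5
Bosnia & Herzegovina	Tmin	AM	9.7
Bosnia & Herzegovina	Tmean	AM	15.6
Bosnia & Herzegovina	Rh	AM	64.2
Bosnia & Herzegovina	Sunshine	AM	5.4
Bosnia & Herzegovina	Rad	AM	16.7
Bosnia & Herzegovina	ET0	AM	10
Bosnia & Herzegovina	Rain	AM	289.8
Bulgaria	Tmax	SA	7.5
Bulgaria	Tmin	SA	0.5
Bulgaria	Tmean	SA	4
Bulgaria	Rh	SA	81.7
Bulgaria	Sunshine	SA	3
Bulgaria	Rad	SA	6.9
Bulgaria	ET0	SA	111.2
Bulgaria	Rain	SA	180.8
Bulgaria	Tmax	AM	20.6
Bulgaria	Tmin	AM	11
Bulgaria	Tmean	AM	15.8
Bulgaria	Rh	AM	74
Bulgaria	Sunshine	AM	7.2
Bulgaria	Rad	AM	19.3
Bulgaria	ET0	AM	290.3
Bulgaria	Rain	AM	162.8
Croatia	Tmax	SA	10.1
Croatia	Tmin	SA	3
Croatia	Tmean	SA	6.5
Croatia	Rh	SA	71.6
Croatia	Sunshine	SA	2.3
Croatia	Rad	SA	6
Croatia	ET0	SA	149
Croatia	Rain	SA	397.7
Croatia	Tmax	AM	21.7
Croatia	Tmin	AM	12
Croatia	Tmean	AM	16.8
Croatia	Rh	AM	63.6
Croatia	Sunshine	AM	6.1
Croatia	Rad	AM	17.7
Croatia	ET0	AM	292.7
Croatia	Rain	AM	238.3
Cyprus	Tmax	SA	18.2
Cyprus	Tmin	SA	6.9
Cyprus	Tmean	SA	12.5
Cyprus	Rh	SA	69.7
Cyprus	Sunshine	SA	5.7
Cyprus	Rad	SA	11.4
Cyprus	ET0	SA	213.5
Cyprus	Rain	SA	255.3
Cyprus	Tmax	AM	27.4
Cyprus	Tmin	AM	13
Cyprus	Tmean	AM	20.2
Cyprus	Rh	AM	55.8
Cyprus	Sunshine	AM	9.5
Cyprus	Rad	AM	23.5
Cyprus	ET0	AM	411.6
Cyprus	Rain	AM	27.3
Egypt	Tmax	SA	21.9
Egypt	Tmin	SA	9.8
Egypt	Tmean	SA	15.8
Egypt	Rh	SA	67.5
Egypt	Sunshine	SA	7.1
Egypt	Rad	SA	14.3
Egypt	ET0	SA	333.7
Egypt	Rain	SA	30.6
Egypt	Tmax	AM	31
Egypt	Tmin	AM	16.5
Egypt	Tmean	AM	23.8
Egypt	Rh	AM	49.9
Egypt	Sunshine	AM	9.9
Egypt	Rad	AM	24.4
Egypt	ET0	AM	541
Egypt	Rain	AM	2.2
France	Tmax	SA	11.4
France	Tmin	SA	3.5
France	Tmean	SA	7.4
France	Rh	SA	78.3
France	Sunshine	SA	3.3
France	Rad	SA	6.9
France	ET0	SA	162
France	Rain	SA	255.9
France	Tmax	AM	20.8
France	Tmin	AM	10.4
France	Tmean	AM	15.6
France	Rh	AM	66.8
France	Sunshine	AM	7.1
France	Rad	AM	18.9
France	ET0	AM	335.6
France	Rain	AM	161.8
Greece	Tmax	SA	14.4
Greece	Tmin	SA	6
Greece	Tmean	SA	10.2
Greece	Rh	SA	74.2
Greece	Sunshine	SA	3.2
Greece	Rad	SA	8
Greece	ET0	SA	196.1
Greece	Rain	SA	307.8
Greece	Tmax	AM	24
Greece	Tmin	AM	13.4
Greece	Tmean	AM	18.7
Greece	Rh	AM	64
Greece	Sunshine	AM	6.1
Greece	Rad	AM	16.5
Greece	ET0	AM	313.8
Greece	Rain	AM	82.5
Israel	Tmax	SA	18.7
Israel	Tmin	SA	8.4
Israel	Tmean	SA	13.5
Israel	Rh	SA	72
Israel	Sunshine	SA	6.8
Israel	Rad	SA	13.2
Israel	ET0	SA	292.1
Israel	Rain	SA	442.9
Israel	Tmax	AM	27.8
Israel	Tmin	AM	14.1
Israel	Tmean	AM	20.9
Israel	Rh	AM	56.2
Israel	Sunshine	AM	10.9
Israel	Rad	AM	25.7
Israel	ET0	AM	542.4
Israel	Rain	AM	31.2
Italy	Tmax	SA	14
Italy	Tmin	SA	6.8
Italy	Tmean	SA	10.4
Italy	Rh	SA	75.7
Italy	Sunshine	SA	3.6
Italy	Rad	SA	7.9
Italy	ET0	SA	180.2
Italy	Rain	SA	282.7
Italy	Tmax	AM	22.5
Italy	Tmin	AM	13.2
Italy	Tmean	AM	17.9
Italy	Rh	AM	68.6
Italy	Sunshine	AM	7.8
Italy	Rad	AM	20.3
Italy	ET0	AM	335.6
Italy	Rain	AM	104.2
Jordan	Tmax	SA	19.6
Jordan	Tmin	SA	7.8
Jordan	Tmean	SA	13.7
Jordan	Rh	SA	58.9
Jordan	Sunshine	SA	6.1
Jordan	Rad	SA	12.7
Jordan	ET0	SA	332.3
Jordan	Rain	SA	165.4
Jordan	Tmax	AM	30.3
Jordan	Tmin	AM	14.7
Jordan	Tmean	AM	22.5
Jordan	Rh	AM	45.1
Jordan	Sunshine	AM	9.1
Jordan	Rad	AM	23.1
Jordan	ET0	AM	535.8
Jordan	Rain	AM	13.5
Lebanon	Tmax	SA	17.9
Lebanon	Tmin	SA	10.1
Lebanon	Tmean	SA	14
Lebanon	Rh	SA	67
Lebanon	Sunshine	SA	4.3
Lebanon	Rad	SA	10.1
Lebanon	ET0	SA	292
Lebanon	Rain	SA	722.7
Lebanon	Tmax	AM	23.9
Lebanon	Tmin	AM	15.4
Lebanon	Tmean	AM	19.6
Lebanon	Rh	AM	66.1
Lebanon	Sunshine	AM	8.4
Lebanon	Rad	AM	21.9
Lebanon	ET0	AM	404.1
Lebanon	Rain	AM	79
Libya	Tmax	SA	19.6
Libya	Tmin	SA	8.8
Libya	Tmean	SA	14.2
Libya	Rh	SA	65.4
Libya	Sunshine	SA	6.1
Libya	Rad	SA	12.6
Libya	ET0	SA	324.9
Libya	Rain	SA	123.2
Libya	Tmax	AM	27.8
Libya	Tmin	AM	15.4
Libya	Tmean	AM	21.6
Libya	Rh	AM	59.8
Libya	Sunshine	AM	8.7
Libya	Rad	AM	22.5
Libya	ET0	AM	456.3
Libya	Rain	AM	14.3
Macedonia	Tmax	SA	8.2
Macedonia	Tmin	SA	-0.9
Macedonia	Tmean	SA	3.6
Macedonia	Rh	SA	81.3
Macedonia	Sunshine	SA	2.1
Macedonia	Rad	SA	6.4
Macedonia	ET0	SA	100.2
Macedonia	Rain	SA	228.2
Macedonia	Tmax	AM	22.5
Macedonia	Tmin	AM	9
Macedonia	Tmean	AM	15.7
Macedonia	Rh	AM	64.7
Macedonia	Sunshine	AM	6.3
Macedonia	Rad	AM	18.3
Macedonia	ET0	AM	296
Macedonia	Rain	AM	142.1
Morocco	Tmax	SA	18.9
Morocco	Tmin	SA	7.2
Morocco	Tmean	SA	13
Morocco	Rh	SA	69.8
Morocco	Sunshine	SA	5.9
Morocco	Rad	SA	12.1
Morocco	ET0	SA	262.7
Morocco	Rain	SA	227.6
Morocco	Tmax	AM	25.1
Morocco	Tmin	AM	12.2
Morocco	Tmean	AM	18.6
Morocco	Rh	AM	66.1
Morocco	Sunshine	AM	8.7
Morocco	Rad	AM	22.4
Morocco	ET0	AM	364.9
Morocco	Rain	AM	84
Portugal	Tmax	SA	11.7
Portugal	Tmin	SA	3.7
Portugal	Tmean	SA	7.7
Portugal	Rh	SA	77.3
Portugal	Sunshine	SA	4.7
Portugal	Rad	SA	9.1
Portugal	ET0	SA	174.8
Portugal	Rain	SA	630.4
Portugal	Tmax	AM	19.6
Portugal	Tmin	AM	8.5
Portugal	Tmean	AM	14.1
Portugal	Rh	AM	63.6
Portugal	Sunshine	AM	8.5
Portugal	Rad	AM	21.4
Portugal	ET0	AM	343.3
Portugal	Rain	AM	227.7
Romania	Tmax	SA	6.4
Romania	Tmin	SA	-1
Romania	Tmean	SA	2.7
Romania	Rh	SA	88.7
Romania	Sunshine	SA	3.1
Romania	Rad	SA	6.5
Romania	ET0	SA	3.6
Romania	Rain	SA	200
Romania	Tmax	AM	21.5
Romania	Tmin	AM	10.4
Romania	Tmean	AM	15.9
Romania	Rh	AM	72.8
Romania	Sunshine	AM	7.8
Romania	Rad	AM	19.8
Romania	ET0	AM	10.8
Romania	Rain	AM	170
Serbia	Tmax	SA	7.7
Serbia	Tmin	SA	-0.1
Serbia	Tmean	SA	3.8
Serbia	Rh	SA	79.7
Serbia	Sunshine	SA	1.8
Serbia	Rad	SA	5.8
Serbia	ET0	SA	96
Serbia	Rain	SA	215.2
Serbia	Tmax	AM	21.8
Serbia	Tmin	AM	10.3
Serbia	Tmean	AM	16.1
Serbia	Rh	AM	65.7
Serbia	Sunshine	AM	5.7
Serbia	Rad	AM	17.2
Serbia	ET0	AM	278.1
Serbia	Rain	AM	216
Spain	Tmax	SA	13
Spain	Tmin	SA	4
Spain	Tmean	SA	8.5
Spain	Rh	SA	77.5
Spain	Sunshine	SA	3.9
Spain	Rad	SA	8.4
Spain	ET0	SA	163.3
Spain	Rain	SA	226.4
Spain	Tmax	AM	23
Spain	Tmin	AM	10.5
Spain	Tmean	AM	16.8
Spain	Rh	AM	58.5
Spain	Sunshine	AM	7.8
Spain	Rad	AM	20.4
Spain	ET0	AM	357.9
Spain	Rain	AM	119
Syria	Tmax	SA	15.4
Syria	Tmin	SA	4.4
Syria	Tmean	SA	9.9
Syria	Rh	SA	71.7
Syria	Sunshine	SA	5.1
Syria	Rad	SA	10.6
Syria	ET0	SA	212.8
Syria	Rain	SA	178.8
Syria	Tmax	AM	29.7
Syria	Tmin	AM	14.7
Syria	Tmean	AM	22.2
Syria	Rh	AM	44.1
Syria	Sunshine	AM	9.2
Syria	Rad	AM	23
Syria	ET0	AM	580.2
Syria	Rain	AM	38.8
Tunisia	Tmax	SA	17.9
Tunisia	Tmin	SA	8.3
Tunisia	Tmean	SA	13.1
Tunisia	Rh	SA	72.7
Tunisia	Sunshine	SA	5.6
Tunisia	Rad	SA	11.1
Tunisia	ET0	SA	244.6
Tunisia	Rain	SA	182.5
Tunisia	Tmax	AM	26
Tunisia	Tmin	AM	14.7
Tunisia	Tmean	AM	20.3
Tunisia	Rh	AM	67.5
Tunisia	Sunshine	AM	8.5
Tunisia	Rad	AM	21.9
Tunisia	ET0	AM	393.9
Tunisia	Rain	AM	45.6
Turkey	Tmax	SA	13
Turkey	Tmin	SA	4.5
Turkey	Tmean	SA	8.8
Turkey	Rh	SA	69.4
Turkey	Sunshine	SA	3.8
Turkey	Rad	SA	8.6
Turkey	ET0	SA	172.7
Turkey	Rain	SA	400.9
Turkey	Tmax	AM	24.3
Turkey	Tmin	AM	13.2
Turkey	Tmean	AM	18.7
Turkey	Rh	AM	61.6
Turkey	Sunshine	AM	8
Turkey	Rad	AM	20.9
Turkey	ET0	AM	356
Turkey	Rain	AM	131.6
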