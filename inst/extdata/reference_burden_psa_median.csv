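country_code,country,cost_median_musd,cost_lo_musd,cost_hi_musd,icu_days_median,gw_days_median,readmissions_median
FRA,France,12.97,8.32,27.18,1900,9500,430
DEU,Germany,43.57,28.06,81.82,6300,33500,1450
ITA,Italy,20.37,11.63,33.93,3100,17000,600
GBR,United Kingdom,12.34,8.47,18.93,1800,9800,290
NLD,Netherlands,12.97,9.24,21.41,2200,12300,230
ESP,Spain,8.69,4.81,13.24,1200,7000,280
AUS,Australia,13.13,6.63,17.35,1900,10800,260
ISR,Israel,3.24,2.24,5.61,600,3400,70
JPN,Japan,47.25,27.78,77.85,8500,50000,320
BRA,Brazil,16.12,9.86,23.33,2900,16300,520
CAN,Canada,29.49,19.42,50.31,3200,17300,490
TWN,Taiwan,1.85,1.29,3.44,400,2300,40
THA,Thailand,7.58,3.43,12.58,1400,7900,160
USA,United States,299.40,179.03,528.94,22600,125100,4280
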