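country_code,country,procedures,swi_events,total_cost,cost_per_swi,cost_per_cabg
FRA,France,19280,717,8496817,11845,441
DEU,Germany,50472,2836,36876758,13003,731
ITA,Italy,20930,1378,18940618,13741,905
GBR,United Kingdom,16529,539,7200434,13357,436
NLD,Netherlands,9685,814,18365837,22551,1896
ESP,Spain,8294,726,8715780,12008,1051
AUS,Australia,13063,535,11683094,21831,894
ISR,Israel,4037,150,2323092,15508,575
JPN,Japan,21313,1099,59566162,54180,2795
BRA,Brazil,20198,1223,9996520,8172,495
CAN,Canada,20868,1239,33091101,26707,1586
TWN,Taiwan,1510,103,1467327,14249,971
THA,Thailand,6581,518,4972120,9600,756
USA,United States,159063,9139,336028904,36768,2113
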