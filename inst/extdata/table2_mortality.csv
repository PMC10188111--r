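sex,site,n,deaths,person_years,rate_printed,ci_low_printed,ci_high_printed
male,no_fracture,698443,231507,9049194,2.6,2.5,2.6
male,any_fracture,95372,41017,626733,6.5,6.5,6.6
male,hip,25706,16890,107789,15.7,15.4,15.9
male,femur,1910,997,10468,9.5,8.9,10.1
male,pelvis,1305,751,6465,11.6,10.8,12.5
male,vertebrae,6924,3125,41746,7.5,7.2,7.7
male,humerus,10126,4827,62350,7.7,7.5,8.0
male,rib,6867,2350,50186,4.7,4.5,4.9
male,clavicle,5201,1636,39731,4.1,3.9,4.3
male,lower_leg,6296,1796,52915,3.4,3.2,3.6
male,forearm,15268,4675,120719,3.9,3.8,4.0
male,knee,1382,447,10886,4.1,3.7,4.5
male,ankle,1084,275,9081,3.0,2.7,3.4
male,hand,8309,2178,70263,3.1,3.0,3.2
male,foot,4994,1070,44136,2.4,2.3,2.6
female,no_fracture,661026,195467,8723863,2.2,2.2,2.3
female,any_fracture,212498,81727,1506940,5.4,5.4,5.5
female,hip,51669,31816,259087,12.3,12.1,12.4
female,femur,3529,1921,19322,9.9,9.5,10.4
female,pelvis,4920,2893,26761,10.8,10.4,11.2
female,vertebrae,9732,4658,60295,7.7,7.5,7.9
female,humerus,28298,10330,202662,5.1,5.0,5.2
female,rib,3153,1218,22285,5.5,5.2,5.8
female,clavicle,4480,1577,31755,5.0,4.7,5.2
female,lower_leg,11460,3130,94308,3.3,3.2,3.4
female,forearm,68333,18470,559406,3.3,3.2,3.3
female,knee,2604,629,21085,3.0,2.8,3.2
female,ankle,1936,499,15726,3.2,2.9,3.5
female,hand,12489,2681,108112,2.5,2.4,2.6
female,foot,9916,1904,86136,2.2,2.1,2.3
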