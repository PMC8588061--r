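family,H,SpO2,HR,BF,bg
mpr4-span,450,96,60,5,1.8399999999999999
mpr4-span,500,96,60,5,6.5899999999999999
mpr4-span,550,96,60,5,11.3399999999999999
mpr4-span,450,96,100,5,2.4000000000000004
mpr4-span,500,96,100,5,7.1500000000000004
mpr4-span,550,96,100,5,11.8999999999999986
mpr4-span,450,96,60,25,3.3199999999999998
mpr4-span,500,96,60,25,8.0700000000000003
mpr4-span,550,96,60,25,12.8200000000000003
mpr4-span,450,96,100,25,4.2000000000000002
mpr4-span,500,96,100,25,8.9499999999999993
mpr4-span,550,96,100,25,13.6999999999999993
saturating,450,96,60,5,3.8392365002224338
saturating,500,96,60,5,6.9900000000000002
saturating,550,96,60,5,10.1407634997775649
saturating,450,96,100,5,3.9992365002224339
saturating,500,96,100,5,7.1499999999999995
saturating,550,96,100,5,10.3007634997775650
saturating,450,96,60,25,3.8392365002224338
saturating,500,96,60,25,6.9900000000000002
saturating,550,96,60,25,10.1407634997775649
saturating,450,96,100,25,3.9992365002224339
saturating,500,96,100,25,7.1499999999999995
saturating,550,96,100,25,10.3007634997775650
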