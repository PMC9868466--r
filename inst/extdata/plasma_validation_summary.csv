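level_id,spiked,measured,cv_within_pct,srb_pct,rb_pct,ab_pct,teo_sr,teo_rb,teo_ab
L1,0.4,0.6,12.0,-40.9,19.1,9.9,64.9,43.1,33.9
L2,0.7,0.9,7.7,-22.5,19.1,9.9,37.8,34.5,15.4
L3,1.0,1.3,9.8,-7.2,19.1,9.9,26.8,38.7,19.6
L4,2.0,2.2,4.5,-9.0,7.3,9.9,18.0,16.3,9.0
L5,5.0,5.0,5.2,-7.6,5.0,9.9,18.0,15.4,10.4
L6,7.0,6.6,3.7,-10.3,9.2,9.9,17.6,16.6,7.4
L7,10.0,8.9,3.2,-14.8,8.3,9.9,21.1,14.7,6.4
L8,15.0,13.0,7.4,-15.8,8.3,9.9,30.7,23.1,14.8
L9,20.0,17.7,4.3,-13.2,8.3,9.9,21.8,16.9,8.6
L10,30.0,25.3,4.7,-16.9,8.3,9.9,26.3,17.7,9.4
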