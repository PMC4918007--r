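landmark,name,x,y
1,snout_tip,0.0,0.0
2,dorsal_head_above_eye,3.0,2.6
3,dorsal_fin_origin,13.5,3.2
4,dorsal_fin_insertion,17.0,2.6
5,dorsal_caudal_peduncle,22.0,1.6
6,caudal_fin_base_mid,24.0,0.0
7,ventral_caudal_peduncle,22.0,-1.5
8,anal_fin_insertion,16.5,-2.4
9,anal_fin_origin,13.0,-2.9
10,pelvic_fin_origin,9.0,-3.0
11,pectoral_fin_insertion,6.0,-2.6
12,lower_jaw_tip,1.5,-1.1
13,eye_center,2.6,0.7
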