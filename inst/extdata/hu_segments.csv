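"hu_low","hu_high","material","nominal_density","density_slope"
-1000,-950,"air",0.00121,0
-950,-120,"lung",0.465647,0.00099879
-120,-70,"adipose_low",0.905115,0.00099879
-70,-20,"adipose_high",0.955054,0.00099879
-20,0,"soft_adipose_mix",0.990012,0.00099879
0,18,"muscle_low",1.0054,6e-04
18,80,"muscle_high",1.0294,6e-04
80,120,"connective",1.06,6e-04
120,222.424242424242,"bone_01",1.102727,6e-04
222.424242424242,324.848484848485,"bone_01",1.164182,6e-04
324.848484848485,427.272727272727,"bone_02",1.225636,6e-04
427.272727272727,529.69696969697,"bone_02",1.287091,6e-04
529.69696969697,632.121212121212,"bone_03",1.348545,6e-04
632.121212121212,734.545454545455,"bone_03",1.41,6e-04
734.545454545455,836.969696969697,"bone_04",1.471455,6e-04
836.969696969697,939.393939393939,"bone_04",1.532909,6e-04
939.393939393939,1041.81818181818,"bone_05",1.594364,6e-04
1041.81818181818,1144.24242424242,"bone_05",1.655818,6e-04
1144.24242424242,1246.66666666667,"bone_06",1.717273,6e-04
1246.66666666667,1349.09090909091,"bone_06",1.778727,6e-04
1349.09090909091,1451.51515151515,"bone_07",1.840182,6e-04
1451.51515151515,1553.93939393939,"bone_07",1.901636,6e-04
1553.93939393939,1656.36363636364,"bone_08",1.963091,6e-04
1656.36363636364,1758.78787878788,"bone_08",2.024545,6e-04
1758.78787878788,1861.21212121212,"bone_09",2.086,6e-04
1861.21212121212,1963.63636363636,"bone_09",2.147455,6e-04
1963.63636363636,2066.06060606061,"bone_10",2.208909,6e-04
2066.06060606061,2168.48484848485,"bone_10",2.270364,6e-04
2168.48484848485,2270.90909090909,"bone_11",2.331818,6e-04
2270.90909090909,2373.33333333333,"bone_11",2.393273,6e-04
2373.33333333333,2475.75757575758,"bone_12",2.454727,6e-04
2475.75757575758,2578.18181818182,"bone_12",2.516182,6e-04
2578.18181818182,2680.60606060606,"bone_13",2.577636,6e-04
2680.60606060606,2783.0303030303,"bone_13",2.639091,6e-04
2783.0303030303,2885.45454545455,"bone_14",2.700545,6e-04
2885.45454545455,2987.87878787879,"bone_14",2.762,6e-04
2987.87878787879,3090.30303030303,"bone_15",2.823455,6e-04
3090.30303030303,3192.72727272727,"bone_15",2.884909,6e-04
3192.72727272727,3295.15151515152,"bone_16",2.946364,6e-04
3295.15151515152,3397.57575757576,"bone_16",3.007818,6e-04
3397.57575757576,3500,"bone_16",3.069273,6e-04
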