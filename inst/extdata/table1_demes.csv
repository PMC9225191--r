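name,date,easting,northing,area,n,NA_,AR,HO,HE,FIS,HWE_p
1-Vegadali,2011-09,298049,4804471,2.31,18,6.09,5.35,0.636,0.695,0.087,0.031
2-Ceceda,2012-12,302152,4803618,5.95,14,4.82,4.53,0.604,0.629,0.042,0.434
3-Fresnadiello,2011-06,302809,4805229,2.84,14,6.00,5.40,0.656,0.692,0.052,0.207
4-Poreño,2012-07,301923,4812449,7.58,11,4.64,4.64,0.612,0.614,0.005,0.610
5-Serida,2011-06,302393,4816492,7.26,12,4.64,4.47,0.458,0.556,0.183,<0.001
6-Priesca,2011-04,309079,4817418,2.03,14,3.55,3.44,0.591,0.554,-0.071,0.582
7-Rozada,2012-03,305277,4820835,2.99,14,3.91,3.75,0.524,0.542,0.034,0.467
8-Oles,2011-06,301922,4822568,4.55,15,4.00,3.40,0.491,0.595,0.180,<0.001
9-Teleña,2012-07,304030,4823030,1.13,14,3.82,3.75,0.656,0.612,-0.075,0.545
10-Marina,2012-07,304955,4823559,1.00,11,3.91,3.91,0.595,0.587,-0.015,0.528
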