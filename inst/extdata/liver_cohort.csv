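patient_id,avg_voxels,delta_vol_pct,avg_mean_adc,delta_adc_pct,lesion_note,motion_flag
1,1141,0.44,76,18.56,,TRUE
2,3214,8.47,102,-22.37,Sub-phrenic,TRUE
3,2845,0.21,97,1.17,5% cystic,FALSE
4,1297,0.15,77,14.69,,FALSE
5,603,4.81,98,-3.39,Sub-phrenic,TRUE
6,573,2.44,87,-2.52,,FALSE
7,148,-14.63,123,2.25,,FALSE
8,3178,-1.48,102,7.60,Sub-phrenic,TRUE
9,4589,1.44,95,-4.35,,FALSE
10,3731,28.19,103,1.69,,FALSE
11,5957,0.32,140,6.48,,FALSE
12,74572,-6.04,102,-12.13,,TRUE
13,6780,-4.09,93,1.22,,FALSE
14,270,-5.57,93,-7.36,,FALSE
15,61130,-5.01,118,-1.11,,FALSE
16,8788,4.79,127,-5.30,10% cystic,FALSE
17,4315,-4.82,98,1.06,,FALSE
18,2140,-2.38,129,1.04,,FALSE
19,7914,8.38,198,2.84,95% cystic,FALSE
20,4304,-3.53,110,-0.31,,FALSE
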