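alignment,activity,condyle,f_med,f_ant,f_dist,f_res
varus,gait,medial,-3,-15,232,233
varus,gait,lateral,-7,6,100,100
varus,SD,medial,-9,9,294,294
varus,SD,lateral,-18,-3,145,147
varus,DKB,medial,-9,6,114,115
varus,DKB,lateral,-17,0,211,211
neutral,gait,medial,14,-12,177,178
neutral,gait,lateral,0,0,162,162
neutral,SD,medial,9,12,218,218
neutral,SD,lateral,-9,-7,222,223
neutral,DKB,medial,3,6,95,95
neutral,DKB,lateral,-5,-7,231,232
valgus,gait,medial,26,-8,194,196
valgus,gait,lateral,9,-2,137,137
valgus,SD,medial,21,8,259,260
valgus,SD,lateral,1,-4,175,175
valgus,DKB,medial,32,13,269,271
valgus,DKB,lateral,2,-6,36,37
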