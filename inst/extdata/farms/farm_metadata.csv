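"farm_id","location","system","species","purpose","timestamp"
1,"indoor","RAS","rainbow trout","grow-out","2019-07-01"
2,"indoor","RAS","rainbow trout","grow-out","2019-07-01"
3,"outdoor","FTS","rainbow trout","grow-out","2019-07-01"
4,"outdoor","FTS","rainbow trout","restocking","2019-07-01"
5,"indoor","RAS","pikeperch","grow-out","2019-07-01"
6,"indoor","RAS","pikeperch","grow-out","2019-07-01"
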