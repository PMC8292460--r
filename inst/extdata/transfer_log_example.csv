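object_id,outcome
1,success
2,success
3,success
4,pick_up_error
5,success
6,expel_error
7,success
8,double_pick
9,success
10,success
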