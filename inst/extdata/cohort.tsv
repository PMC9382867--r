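sample_id	family_id	affected
1-b	F1	1
2-a	F2	1
2-b	F2	1
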