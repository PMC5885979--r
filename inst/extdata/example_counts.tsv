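feature_id	S1	S2	S3
F1	10	5	20
F2	20	10	40
F3	0	15	0
F4	40	0	80
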