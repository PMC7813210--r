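word	weight	side
贵	1.0	expensive
太贵	2.0	expensive
昂贵	1.5	expensive
贵死	1.8	expensive
偏贵	1.2	expensive
吃不消	1.4	expensive
便宜	1.0	cheap
实惠	1.2	cheap
划算	1.3	cheap
亲民	1.1	cheap
合理	1.0	cheap
超值	0.8	cheap
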