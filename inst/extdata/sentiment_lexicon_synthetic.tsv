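word	value
好	1.0
满意	1.5
安全	1.2
放心	1.3
有效	1.0
点赞	0.8
支持	1.0
差	-1.0
担心	-1.2
危险	-1.5
害怕	-1.3
难受	-1.1
反对	-1.0
糟糕	-1.4
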