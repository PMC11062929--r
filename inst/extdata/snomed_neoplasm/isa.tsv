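child_id	parent_id
126992002	npn-trunk
126992002	n-abdomen
188326001	npn-trunk
188326001	n-abdomen
benign-ganglioneuroma-abdomen	npn-trunk
benign-ganglioneuroma-abdomen	n-abdomen
morph-malignant	morph-neoplasm
morph-ganglioneuroma	morph-neoplasm
site-pn-abdomen	site-pn-trunk
site-pn-abdomen	site-abdomen
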