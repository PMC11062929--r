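source_id	group_index	attribute_id	value_id
126992002	1	assoc-morph	morph-neoplasm
126992002	1	finding-site	site-pn-abdomen
188326001	1	assoc-morph	morph-malignant
188326001	1	finding-site	site-pn-abdomen
benign-ganglioneuroma-abdomen	1	assoc-morph	morph-ganglioneuroma
benign-ganglioneuroma-abdomen	1	finding-site	site-pn-abdomen
npn-trunk	1	assoc-morph	morph-neoplasm
npn-trunk	1	finding-site	site-pn-trunk
n-abdomen	1	assoc-morph	morph-neoplasm
n-abdomen	1	finding-site	site-abdomen
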