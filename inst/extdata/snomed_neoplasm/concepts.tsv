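id	name	definition_status	active
116680003	Is a (attribute)	primitive	TRUE
assoc-morph	Associated morphology (attribute)	primitive	TRUE
finding-site	Finding site (attribute)	primitive	TRUE
morph-neoplasm	Neoplasm (morphologic abnormality)	primitive	TRUE
morph-malignant	Malignant neoplasm of primary, secondary, or uncertain origin (morphologic abnormality)	primitive	TRUE
morph-ganglioneuroma	Ganglioneuroma (morphologic abnormality)	primitive	TRUE
site-pn-abdomen	Structure of peripheral nerve of abdomen (body structure)	primitive	TRUE
site-pn-trunk	Structure of peripheral nerve of trunk (body structure)	primitive	TRUE
site-abdomen	Abdominal structure (body structure)	primitive	TRUE
npn-trunk	Neoplasm of peripheral nerves of trunk (disorder)	primitive	TRUE
n-abdomen	Neoplasm of abdomen (disorder)	primitive	TRUE
126992002	Neoplasm of peripheral nerves of abdomen (disorder)	primitive	TRUE
188326001	Malignant neoplasm of peripheral nerve of abdomen (disorder)	fully_defined	TRUE
benign-ganglioneuroma-abdomen	Benign ganglioneuroma of abdomen (disorder)	fully_defined	TRUE
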