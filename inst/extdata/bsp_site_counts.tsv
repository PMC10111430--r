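amplicon	condition	position	meth_clones	total_clones
plus	vegetative	2524758	0	33
plus	vegetative	2524760	0	33
plus	vegetative	2524803	5	33
plus	vegetative	2524813	0	33
plus	vegetative	2524847	2	33
plus	vegetative	2524849	1	33
plus	vegetative	2524850	2	33
plus	vegetative	2525008	1	33
plus	vegetative	2525071	1	33
plus	developed	2524758	1	37
plus	developed	2524760	2	37
plus	developed	2524803	6	37
plus	developed	2524813	2	37
plus	developed	2524847	1	37
plus	developed	2524849	1	37
plus	developed	2524850	0	37
plus	developed	2525008	3	37
plus	developed	2525071	1	37
minus	vegetative	2524729	1	34
minus	vegetative	2524741	0	34
minus	vegetative	2524753	0	34
minus	vegetative	2524780	0	34
minus	vegetative	2524824	4	34
minus	vegetative	2524889	1	34
minus	vegetative	2524976	1	34
minus	vegetative	2525007	1	34
minus	vegetative	2525038	0	34
minus	vegetative	2525039	0	34
minus	vegetative	2525049	1	34
minus	developed	2524729	0	36
minus	developed	2524741	1	36
minus	developed	2524753	1	36
minus	developed	2524780	2	36
minus	developed	2524824	3	36
minus	developed	2524889	0	36
minus	developed	2524976	1	36
minus	developed	2525007	0	36
minus	developed	2525038	1	36
minus	developed	2525039	1	36
minus	developed	2525049	0	36
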