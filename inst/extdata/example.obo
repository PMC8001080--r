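format-version: 1.4

[Term]
id: EX:0001
name: chemical entity

[Term]
id: EX:0002
name: role

[Term]
id: EX:0010
name: molecular entity
is_a: EX:0001 ! chemical entity

[Term]
id: EX:0011
name: organic molecular entity
is_a: EX:0010 ! molecular entity

[Term]
id: EX:0012
name: oxygen molecular entity
is_a: EX:0011 ! organic molecular entity

[Term]
id: EX:0013
name: carbohydrate
is_a: EX:0012 ! oxygen molecular entity

[Term]
id: EX:0014
name: monosaccharide
is_a: EX:0013 ! carbohydrate

[Term]
id: EX:0015
name: aldose
is_a: EX:0014 ! monosaccharide

[Term]
id: EX:0016
name: hexose
is_a: EX:0015 ! aldose

[Term]
id: EX:0017
name: aldohexose
is_a: EX:0016 ! hexose

[Term]
id: EX:0020
name: glucose
subset: iedb_curated
is_a: EX:0017 ! aldohexose

[Term]
id: EX:0021
name: fructose
subset: iedb_curated
is_a: EX:0014 ! monosaccharide

[Term]
id: EX:0022
name: ribose
subset: iedb_curated
is_a: EX:0014 ! monosaccharide

[Term]
id: EX:0030
name: steroid
is_a: EX:0011 ! organic molecular entity

[Term]
id: EX:0023
name: progesterone
subset: iedb_curated
is_a: EX:0030 ! steroid
relationship: has_role EX:0101 ! hormone

[Term]
id: EX:0100
name: biological role
is_a: EX:0002 ! role

[Term]
id: EX:0101
name: hormone
is_a: EX:0100 ! biological role

[Term]
id: EX:0102
name: application
is_a: EX:0002 ! role
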