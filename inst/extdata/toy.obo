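format-version: 1.2
ontology: toy

[Term]
id: GO:0000001
name: term A (root)
namespace: biological_process

[Term]
id: GO:0000002
name: term B
namespace: biological_process
is_a: GO:0000001 ! term A (root)

[Term]
id: GO:0000006
name: term F
namespace: biological_process
is_a: GO:0000001 ! term A (root)

[Term]
id: GO:0000003
name: term C
namespace: biological_process
is_a: GO:0000002 ! term B

[Term]
id: GO:0000004
name: term D
namespace: biological_process
is_a: GO:0000002 ! term B

[Term]
id: GO:0000005
name: term E
namespace: biological_process
is_a: GO:0000002 ! term B
is_a: GO:0000006 ! term F

[Term]
id: GO:0000007
name: dead term
namespace: biological_process
is_obsolete: true

[Term]
id: GO:0000008
name: other-branch term
namespace: molecular_function

[Typedef]
id: part_of
name: part of
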