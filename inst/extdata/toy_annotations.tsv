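gene	term
a	GO:0000001
b	GO:0000002
c	GO:0000003
d	GO:0000004
e	GO:0000005
f	GO:0000006
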