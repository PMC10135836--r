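egg_id,bands,survival
1,552,+
2,552,+
3,552,+
4,552;358,+
5,552,+
6,552;358,+
7,552;358,+
8,552;358,+
9,552,+
10,552;358,+
11,552;358,+
12,552,+
13,552,+
14,552;358,+
15,,N/A
16,552,+
17,552;358,+
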