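egg_id,survival,sex,source
1,+,M,pcr
2,+,M,pcr
3,+,M,pcr
4,+,F,pcr
5,+,M,pcr
6,+,F,pcr
7,+,F,pcr
8,+,F,pcr
9,+,M,pcr
10,+,F,pcr
11,+,F,pcr
12,+,M,pcr
13,+,M,pcr
14,+,F,pcr
15,N/A,N/A,pcr
16,+,M,pcr
17,+,F,pcr
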