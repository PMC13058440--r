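area_a,area_b,precedence,ambiguous
10,11,present,FALSE
10,13,present,FALSE
10,14,present,FALSE
10,24,present,TRUE
10,25,present,FALSE
10,32,present,FALSE
10,44,absent,FALSE
10,45,present,FALSE
10,46,present,FALSE
10,47,present,FALSE
10,8,present,TRUE
10,9,present,FALSE
10,9/46,present,FALSE
11,13,present,FALSE
11,14,present,FALSE
11,24,present,FALSE
11,25,absent,FALSE
11,32,present,FALSE
11,44,absent,FALSE
11,45,present,FALSE
11,46,absent,FALSE
11,47,present,FALSE
11,8,absent,FALSE
11,9,present,FALSE
11,9/46,present,FALSE
13,14,present,FALSE
13,24,present,FALSE
13,25,present,FALSE
13,32,absent,TRUE
13,44,absent,FALSE
13,45,present,FALSE
13,46,absent,FALSE
13,47,present,FALSE
13,8,present,FALSE
13,9,present,TRUE
13,9/46,present,FALSE
14,24,present,FALSE
14,25,present,FALSE
14,32,present,TRUE
14,44,absent,FALSE
14,45,absent,FALSE
14,46,absent,FALSE
14,47,present,FALSE
14,8,present,FALSE
14,9,present,TRUE
14,9/46,present,FALSE
24,25,present,FALSE
24,32,present,FALSE
24,44,absent,FALSE
24,45,present,FALSE
24,46,present,FALSE
24,47,present,FALSE
24,8,present,FALSE
24,9,present,FALSE
24,9/46,present,TRUE
25,32,present,FALSE
25,44,absent,FALSE
25,45,absent,FALSE
25,46,absent,FALSE
25,47,absent,TRUE
25,8,absent,FALSE
25,9,absent,FALSE
25,9/46,absent,FALSE
32,44,present,FALSE
32,45,present,FALSE
32,46,present,FALSE
32,47,present,FALSE
32,8,present,FALSE
32,9,present,FALSE
32,9/46,present,TRUE
44,45,present,FALSE
44,46,present,FALSE
44,47,present,FALSE
44,8,present,FALSE
44,9,present,FALSE
44,9/46,present,FALSE
45,46,present,FALSE
45,47,present,FALSE
45,8,present,TRUE
45,9,present,FALSE
45,9/46,present,FALSE
46,47,present,FALSE
46,8,present,FALSE
46,9,present,FALSE
46,9/46,present,FALSE
47,8,present,TRUE
47,9,present,FALSE
47,9/46,present,FALSE
8,9,present,FALSE
8,9/46,present,FALSE
9,9/46,present,FALSE
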