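area_a,area_b,label,fp_subtype,ambiguous
10,11,RTP,none,FALSE
10,13,RTP,none,FALSE
10,14,RTP,none,FALSE
10,24,TP,none,TRUE
10,25,RTP,none,FALSE
10,32,RTP,none,FALSE
10,44,TN,none,FALSE
10,45,TP,none,FALSE
10,46,TP,none,FALSE
10,47,RTP,none,FALSE
10,8,RTP,none,TRUE
10,9,RTP,none,FALSE
10,9/46,RTP,none,FALSE
11,13,RTP,none,FALSE
11,14,RTP,none,FALSE
11,24,FN,none,FALSE
11,25,TN,none,FALSE
11,32,FP,implausible_with_precedence,FALSE
11,44,TN,none,FALSE
11,45,FP,implausible_with_precedence,FALSE
11,46,TN,none,FALSE
11,47,RTP,none,FALSE
11,8,TN,none,FALSE
11,9,FP,implausible_with_precedence,FALSE
11,9/46,FN,none,FALSE
13,14,RTP,none,FALSE
13,24,FN,none,FALSE
13,25,FN,none,FALSE
13,32,TN,none,TRUE
13,44,TN,none,FALSE
13,45,FN,none,FALSE
13,46,TN,none,FALSE
13,47,RTP,none,FALSE
13,8,FN,none,FALSE
13,9,FP,implausible_with_precedence,TRUE
13,9/46,FN,none,FALSE
14,24,TP,none,FALSE
14,25,RTP,none,FALSE
14,32,TP,none,TRUE
14,44,TN,none,FALSE
14,45,TN,none,FALSE
14,46,TN,none,FALSE
14,47,RTP,none,FALSE
14,8,FN,none,FALSE
14,9,FP,implausible_with_precedence,TRUE
14,9/46,FN,none,FALSE
24,25,RTP,none,FALSE
24,32,RTP,none,FALSE
24,44,FP,no_precedence,FALSE
24,45,FN,none,FALSE
24,46,FN,none,FALSE
24,47,FN,none,FALSE
24,8,TP,none,FALSE
24,9,RTP,none,FALSE
24,9/46,FP,implausible_with_precedence,TRUE
25,32,RTP,none,FALSE
25,44,TN,none,FALSE
25,45,TN,none,FALSE
25,46,TN,none,FALSE
25,47,FP,no_precedence,TRUE
25,8,TN,none,FALSE
25,9,TN,none,FALSE
25,9/46,TN,none,FALSE
32,44,FP,implausible_with_precedence,FALSE
32,45,FP,implausible_with_precedence,FALSE
32,46,FP,implausible_with_precedence,FALSE
32,47,FP,implausible_with_precedence,FALSE
32,8,RTP,none,FALSE
32,9,RTP,none,FALSE
32,9/46,FP,implausible_with_precedence,TRUE
44,45,RTP,none,FALSE
44,46,RTP,none,FALSE
44,47,RTP,none,FALSE
44,8,RTP,none,FALSE
44,9,TP,none,FALSE
44,9/46,RTP,none,FALSE
45,46,TP,none,FALSE
45,47,RTP,none,FALSE
45,8,RTP,none,TRUE
45,9,RTP,none,FALSE
45,9/46,RTP,none,FALSE
46,47,RTP,none,FALSE
46,8,RTP,none,FALSE
46,9,RTP,none,FALSE
46,9/46,RTP,none,FALSE
47,8,RTP,none,TRUE
47,9,RTP,none,FALSE
47,9/46,RTP,none,FALSE
8,9,RTP,none,FALSE
8,9/46,RTP,none,FALSE
9,9/46,RTP,none,FALSE
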