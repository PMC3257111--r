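# Printed binding affinities (Ki, nM) of the 20 representative N-substituted
# spiropiperidine NOP-receptor agonists. test_set marks compounds footnoted as
# belonging to the external test set.
id,ki_nM,test_set
5,824.0,FALSE
6,14.0,FALSE
11,2.4,FALSE
16,225.0,FALSE
19,9.0,FALSE
26,250.0,FALSE
30,14.5,FALSE
32,0.3,FALSE
36,10.8,TRUE
39,8.4,TRUE
44,57,TRUE
47,53,FALSE
54,18.5,TRUE
69,3.2,FALSE
75,0.5,FALSE
79,1.0,FALSE
87,0.9,FALSE
90,0.9,TRUE
97,0.4,FALSE
103,12.2,FALSE
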