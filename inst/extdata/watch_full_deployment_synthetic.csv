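participant_id,watch_scheduled,watch_initiated
2ba4,9,5
50a8,9,6
996d,7,4
CFD1,9,5
5cd9,9,3
E5b2,9,2
03a7,9,3
2863,11,9
7d78,8,3
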