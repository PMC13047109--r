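participant_id,srh_scheduled,srh_completed,srh_incomplete_participant,srh_incomplete_device,symptom_scheduled,symptom_completed,symptom_incomplete_participant,symptom_incomplete_device,scale_scheduled,scale_completed,scale_incomplete_participant,scale_incomplete_device,watch_scheduled,watch_completed,watch_incomplete_participant,watch_incomplete_device
2ba4,16,16,0,0,5,5,0,0,11,11,0,0,6,4,2,0
1821,11,9,2,0,10,9,1,0,11,9,2,0,5,5,0,0
50a8,16,16,0,0,1,1,0,0,11,11,0,0,6,5,1,0
996d,13,10,3,0,1,1,0,0,10,8,2,0,4,3,0,1
CFD1,11,9,2,0,5,3,2,0,9,8,1,0,7,5,2,0
5cd9,14,12,2,0,6,6,0,0,11,9,2,0,6,2,0,4
E5b2,17,15,2,0,7,4,3,0,11,8,3,0,7,2,2,3
03a7,12,7,5,0,6,6,0,0,11,6,5,0,7,3,4,0
2863,9,9,0,0,8,7,1,0,9,8,1,0,9,8,1,0
7d78,7,5,2,0,4,4,0,0,6,5,1,0,5,3,2,0
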