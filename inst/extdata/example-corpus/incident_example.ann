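T1	Age group 3 10	elderly
T2	People 11 18	patient
T3	Medical condition 24 35	severe pain
T4	Prescribing 40 50	prescribed
T5	Drug dose 51 56	10 mg
T6	Drug name 60 68	morphine
T7	Dose route 81 95	subcutaneously
T8	People 101 106	nurse
T9	Underlying and contributing factors 107 115	covering
T10	People 116 133	multiple patients
T11	Location 139 148	busy ward
T12	Administration 149 161	administered
T13	Dose route 171 184	intravenously
T14	Artefact 190 195	error
T15	Other action 200 210	identified
T16	Date/Time 211 222	immediately
T17	Action taken 243 252	monitored
T18	Medical condition 257 261	harm
T19	Error outcome 262 270	occurred
E1	Prescribing:T4 Subject:T6 Receiver:T2
E2	Administration:T12 Subject:T6 Agent:T8 Receiver:T2
E3	Underlying and contributing factors:T9 Agent:T8 Receiver:T10 Where:T11
E4	Other action:T15 Subject:T14 When:T16
E5	Action taken:T17 Receiver:T2
E6	Error outcome:T19 Subject:T18
R1	has Arg1:T2 Arg2:T3
R2	has dose Arg1:T6 Arg2:T5
R3	has route Arg1:T6 Arg2:T7
R4	has route Arg1:T6 Arg2:T13
R5	at Arg1:T8 Arg2:T11
A1	Action intended but not actual E1
A2	Action not intended but actual E2
A3	Negated E6
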