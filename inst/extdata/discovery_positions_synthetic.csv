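task_id,position
exp01,middle_back
exp02,side
exp03,leading_edge
exp04,leading_edge
exp05,middle_back
exp06,leading_edge
exp07,leading_edge
exp08,middle_back
exp09,leading_edge
exp10,middle_back
exp11,side
exp12,middle_back
exp13,middle_back
exp14,leading_edge
exp15,leading_edge
exp16,middle_back
exp17,leading_edge
exp18,middle_back
exp19,side
exp20,side
exp21,leading_edge
exp22,leading_edge
exp23,side
exp24,middle_back
exp25,leading_edge
exp26,side
exp27,leading_edge
exp28,leading_edge
exp29,leading_edge
exp30,leading_edge
exp31,leading_edge
exp32,leading_edge
exp33,leading_edge
exp34,side
exp35,leading_edge
exp36,leading_edge
exp37,leading_edge
exp38,side
exp39,leading_edge
exp40,side
exp41,middle_back
exp42,side
exp43,leading_edge
exp44,leading_edge
exp45,leading_edge
exp46,side
exp47,leading_edge
exp48,middle_back
exp49,leading_edge
exp50,leading_edge
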