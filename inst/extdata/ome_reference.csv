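bnf_code,name,is_opioid,ome_per_unit_mg,is_regular,ome_per_day_mg
0407020Q0AAAFAF,Morphine sulfate MR 10mg tablets,TRUE,10,TRUE,20
0407020Q0AAAHAH,Morphine sulfate MR 30mg tablets,TRUE,30,TRUE,60
0407020Q0AAAJAJ,Morphine sulfate MR 60mg tablets,TRUE,60,TRUE,120
0407020Q0AAAKAK,Morphine sulfate MR 100mg tablets,TRUE,100,TRUE,200
0407020Q0AAAMAM,Morphine sulfate 10mg/5ml oral solution (5ml dose),TRUE,10,FALSE,0
0407020AFAAAAAA,Oxycodone MR 10mg tablets,TRUE,15,TRUE,30
0407020AFAAACAC,Oxycodone MR 40mg tablets,TRUE,60,TRUE,120
0407020AFAAADAD,Oxycodone 5mg capsules,TRUE,7.5,FALSE,0
0407020A0AAABAB,Fentanyl 25micrograms/hour patches,TRUE,270,TRUE,90
0407020A0AAADAD,Fentanyl 75micrograms/hour patches,TRUE,810,TRUE,270
0407020B0AAAEAE,Buprenorphine 10micrograms/hour patches,TRUE,168,TRUE,24
0407020C0AAAAAA,Tramadol 50mg capsules,TRUE,5,FALSE,0
0407010F0AAAAAA,Codeine 30mg tablets,TRUE,3,FALSE,0
0407010H0AAAAAA,Paracetamol 500mg tablets,FALSE,0,FALSE,0
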