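# Synthetic alignment of 50 sigma70 promoter windows (-35 hexamer, spacer length, -10 hexamer).
# Column base frequencies follow classic consensus-match rates for TTGACA / TATAAT;
# spacer lengths peak at 17 nt. Constructed fixture, not experimental data.
minus35	spacer	minus10
TTGAAG	16	ATTAAT
TTGAAG	17	AATAAT
TTGAAG	17	CATAAT
TTGAAG	17	CATAAT
TTGAAG	17	CATAAT
TTGAAG	17	GATACT
TTGAGG	17	GATACT
TTGAGG	17	GATACT
TTGCGT	17	TATACT
TTGCGT	17	TATACT
TTGCGT	17	TATACT
TTGCGT	17	TATACT
TTGCGT	17	TATACT
TTGCGT	17	TATAGT
TTGCTT	17	TATAGT
TTGGTA	17	TATAGT
TTGGTA	17	TATAGT
TTGGTA	17	TATCGT
TTGGTA	17	TATCGA
TTGGTA	17	TATCGA
TTAGTA	17	TAACGC
TTAGTA	17	TAACTC
TTATCA	17	TAACTG
TTATCA	18	TAACTT
TTATCA	18	TAAGTT
TTATCA	18	TAAGTT
TTCTCA	18	TAAGTT
TTCTCA	18	TAAGTT
TTCTCA	18	TAAGTT
TTCACA	18	TACGTT
TTCACA	18	TACGAT
TTTACA	18	TACTAT
TTTACA	18	TACTAT
TTTACA	19	TACTAT
TATACA	19	TACTAT
TATACA	19	TACTAT
TAGACA	19	TACTAT
TCGACA	15	TAGAAT
TCGACA	15	TAGAAT
ACGACA	15	TAGAAT
AGGACA	15	TAGAAT
AGGACA	16	TAGAAT
AGGACC	16	TAGAAT
CTGACC	16	TAGAAT
CTGACC	16	TATAAT
CTGACC	16	TATAAT
CTGACC	16	TCTAAT
GTGACC	16	TCTAAT
GTGAAC	16	TGTAAT
GTGAAC	16	AGTAAT
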