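gene	class
accD	other
atpA	photosynthesis
atpB	photosynthesis
atpE	photosynthesis
atpF	photosynthesis
atpH	photosynthesis
atpI	photosynthesis
ccsA	photosynthesis
cemA	other
clpP	other
infA	transcription_translation
matK	other
ndhA	photosynthesis
ndhB	photosynthesis
ndhC	photosynthesis
ndhD	photosynthesis
ndhE	photosynthesis
ndhF	photosynthesis
ndhG	photosynthesis
ndhH	photosynthesis
ndhI	photosynthesis
ndhJ	photosynthesis
ndhK	photosynthesis
ndhL	photosynthesis
pafI	photosynthesis
pafII	photosynthesis
petA	photosynthesis
petB	photosynthesis
petD	photosynthesis
petG	photosynthesis
petL	photosynthesis
petN	photosynthesis
psaA	photosynthesis
psaB	photosynthesis
psaC	photosynthesis
psaI	photosynthesis
psaJ	photosynthesis
psbA	photosynthesis
psbB	photosynthesis
psbC	photosynthesis
psbD	photosynthesis
psbE	photosynthesis
psbF	photosynthesis
psbG	photosynthesis
psbH	photosynthesis
psbI	photosynthesis
psbJ	photosynthesis
psbK	photosynthesis
psbL	photosynthesis
psbM	photosynthesis
psbN	photosynthesis
psbT	photosynthesis
psbZ	photosynthesis
rbcL	photosynthesis
rpl14	transcription_translation
rpl16	transcription_translation
rpl2	transcription_translation
rpl20	transcription_translation
rpl21	transcription_translation
rpl22	transcription_translation
rpl23	transcription_translation
rpl32	transcription_translation
rpl33	transcription_translation
rpl36	transcription_translation
rpoA	transcription_translation
rpoB	transcription_translation
rpoC1	transcription_translation
rpoC2	transcription_translation
rps10	transcription_translation
rps11	transcription_translation
rps12	transcription_translation
rps14	transcription_translation
rps15	transcription_translation
rps16	transcription_translation
rps18	transcription_translation
rps19	transcription_translation
rps2	transcription_translation
rps3	transcription_translation
rps4	transcription_translation
rps7	transcription_translation
rps8	transcription_translation
rrn16	transcription_translation
rrn23	transcription_translation
rrn4.5	transcription_translation
rrn5	transcription_translation
trnA-UGC	transcription_translation
trnC-GCA	transcription_translation
trnD-GUC	transcription_translation
trnE-UUC	transcription_translation
trnF-GAA	transcription_translation
trnfM-CAU	transcription_translation
trnG-GCC	transcription_translation
trnG-UCC	transcription_translation
trnH-GUG	transcription_translation
trnI-CAU	transcription_translation
trnI-GAU	transcription_translation
trnK-UUU	transcription_translation
trnL-CAA	transcription_translation
trnL-UAA	transcription_translation
trnL-UAG	transcription_translation
trnM-CAU	transcription_translation
trnN-GUU	transcription_translation
trnP-UGG	transcription_translation
trnQ-UUG	transcription_translation
trnR-ACG	transcription_translation
trnR-UCU	transcription_translation
trnS-GCU	transcription_translation
trnS-GGA	transcription_translation
trnS-UGA	transcription_translation
trnT-GGU	transcription_translation
trnT-UGU	transcription_translation
trnV-GAC	transcription_translation
trnV-UAC	transcription_translation
trnW-CCA	transcription_translation
trnY-GUA	transcription_translation
ycf1	other
ycf15	other
ycf2	other
ycf3	photosynthesis
ycf4	photosynthesis
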