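label	theta	phi
Fp1	90	100.182067403159
Fp2	90	79.8179325968411
F7	90	159.295188945365
F3	59.5294044989533	135
Fz	45	90
F4	59.5294044989533	45
F8	90	20.7048110546354
FC5	69.1211572168754	163.980225892168
FC1	31.3186745409189	135
FC2	31.3186745409189	45
FC6	69.1211572168754	16.0197741078318
T7	90	180
C3	45	180
Cz	0	0
C4	45	0
T8	90	0
TP9	111.865397632601	-171.823461549961
CP5	69.1211572168754	-163.980225892168
CP1	31.3186745409189	-135
CP2	31.3186745409189	-45
CP6	69.1211572168754	-16.0197741078318
TP10	111.865397632601	-8.17653845003925
P7	90	-159.295188945365
P3	59.5294044989533	-135
Pz	45	-90
P4	59.5294044989533	-45
P8	90	-20.7048110546354
PO9	106.652729395454	-153.415031976474
O1	90	-100.182067403159
Oz	90	-90
O2	90	-79.8179325968411
PO10	106.652729395454	-26.5849680235263
AF7	90	147.972239886185
AF3	73.7711833983975	121.141126155195
AF4	73.7711833983975	58.8588738448048
AF8	90	32.027760113815
F5	73.7711833983975	148.858873844805
F1	49.0376131148326	115.41664464194
F2	49.0376131148326	64.5833553580601
F6	73.7711833983975	31.1411261551952
FT9	111.865397632601	171.823461549961
FT7	90	169.817932596841
FC3	49.0376131148326	154.58335535806
FC4	49.0376131148326	25.4166446419399
FT8	90	10.1820674031589
FT10	111.865397632601	8.17653845003925
C5	67.5	180
C1	22.5	180
C2	22.5	0
C6	67.5	0
TP7	90	-169.817932596841
CP3	49.0376131148326	-154.58335535806
CPz	22.5	-90
CP4	49.0376131148326	-25.4166446419399
TP8	90	-10.1820674031589
P5	73.7711833983975	-148.858873844805
P1	49.0376131148326	-115.41664464194
P2	49.0376131148326	-64.5833553580601
P6	73.7711833983975	-31.1411261551952
PO7	90	-147.972239886185
PO3	73.7711833983975	-121.141126155195
POz	67.5	-90
PO4	73.7711833983975	-58.8588738448048
PO8	90	-32.027760113815
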