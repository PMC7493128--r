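Fp1	-0.293892626146237	0.904508497187474	0.309016994374948
Fpz	0	0.951056516295154	0.309016994374948
Fp2	0.293892626146237	0.904508497187474	0.309016994374948
AF7	-0.559016994374947	0.769420884293813	0.309016994374947
AF3	-0.212935129416171	0.80432180307616	0.554729724962376
AF4	0.212935129416171	0.80432180307616	0.554729724962376
AF8	0.559016994374947	0.769420884293814	0.309016994374948
F7	-0.769420884293813	0.559016994374947	0.309016994374947
F5	-0.640706607711279	0.570783310031167	0.513518700560136
F3	-0.459030529989859	0.579959681936844	0.673006493181859
F1	-0.239410277269459	0.585787576969024	0.774296864133209
Fz	-9.34191036099581e-17	0.587785252292473	0.809016994374947
F2	0.239410277269459	0.585787576969024	0.774296864133209
F4	0.459030529989859	0.579959681936844	0.67300649318186
F6	0.640706607711279	0.570783310031167	0.513518700560136
F8	0.769420884293813	0.559016994374947	0.309016994374948
FT7	-0.904508497187474	0.293892626146237	0.309016994374948
FC5	-0.765784151466938	0.300012962899308	0.568829372882976
FC3	-0.55465735272017	0.304851364526034	0.774222750001619
FC1	-0.291089467475268	0.307950375559582	0.905777835960715
FCz	0	0.309016994374947	0.951056516295154
FC2	0.291089467475268	0.307950375559582	0.905777835960716
FC4	0.55465735272017	0.304851364526034	0.774222750001619
FC6	0.765784151466938	0.300012962899308	0.568829372882976
FT8	0.904508497187474	0.293892626146237	0.309016994374947
T7	-0.951056516295154	5.82354159244546e-17	0.309016994374948
C5	-0.809016994374947	3.47410820346109e-17	0.587785252292473
C3	-0.587785252292473	1.60958730917219e-17	0.809016994374947
C1	-0.309016994374947	4.12491205592707e-18	0.951056516295154
Cz	0	0	1
C2	0.309016994374947	4.12491205592707e-18	0.951056516295154
C4	0.587785252292473	1.60958730917219e-17	0.809016994374948
C6	0.809016994374947	3.47410820346109e-17	0.587785252292473
T8	0.951056516295154	5.82354159244546e-17	0.309016994374948
TP7	-0.904508497187474	-0.293892626146236	0.309016994374947
CP5	-0.765784151466938	-0.300012962899308	0.568829372882976
CP3	-0.55465735272017	-0.304851364526034	0.774222750001619
CP1	-0.291089467475269	-0.307950375559582	0.905777835960715
CPz	0	-0.309016994374947	0.951056516295154
CP2	0.291089467475268	-0.307950375559582	0.905777835960716
CP4	0.55465735272017	-0.304851364526034	0.774222750001619
CP6	0.765784151466938	-0.300012962899308	0.568829372882976
TP8	0.904508497187474	-0.293892626146236	0.309016994374948
P7	-0.769420884293814	-0.559016994374947	0.309016994374948
P5	-0.640706607711279	-0.570783310031167	0.513518700560136
P3	-0.459030529989859	-0.579959681936844	0.673006493181859
P1	-0.239410277269459	-0.585787576969024	0.774296864133209
Pz	-4.67095518049791e-17	-0.587785252292473	0.809016994374948
P2	0.239410277269459	-0.585787576969024	0.774296864133209
P4	0.459030529989859	-0.579959681936844	0.67300649318186
P6	0.640706607711279	-0.570783310031167	0.513518700560136
P8	0.769420884293813	-0.559016994374947	0.309016994374948
PO7	-0.559016994374948	-0.769420884293813	0.309016994374947
PO5	-0.405432763084769	-0.790686873244336	0.458735809695019
PO3	-0.212935129416171	-0.80432180307616	0.554729724962376
POz	7.72398351137093e-17	-0.809016994374948	0.587785252292473
PO4	0.212935129416171	-0.80432180307616	0.554729724962376
PO6	0.405432763084769	-0.790686873244336	0.458735809695019
PO8	0.559016994374948	-0.769420884293813	0.309016994374947
O1	-0.293892626146237	-0.904508497187474	0.309016994374948
Oz	1.16470831848909e-16	-0.951056516295154	0.309016994374948
O2	0.293892626146237	-0.904508497187474	0.309016994374948
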