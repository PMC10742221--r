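label	x	y	z
Cz	0	0	1
Fz	3.66796166267921e-17	0.599023598515586	0.800731370948734
C3	-0.599023598515586	7.33592332535841e-17	0.800731370948734
C4	0.599023598515586	0	0.800731370948734
Pz	3.66796166267921e-17	-0.599023598515586	0.800731370948734
FC1	-0.385117954958023	0.385117954958023	0.838670567945424
FC2	0.385117954958023	0.385117954958023	0.838670567945424
CP1	-0.385117954958023	-0.385117954958023	0.838670567945424
CP2	0.385117954958023	-0.385117954958023	0.838670567945424
F3	-0.555656924414492	0.686179155968469	0.469471562785891
F4	0.555656924414493	0.686179155968469	0.469471562785891
P3	-0.555656924414492	-0.686179155968469	0.469471562785891
P4	0.555656924414493	-0.686179155968469	0.469471562785891
FC5	-0.840923027609445	0.356950647590944	0.4067366430758
FC6	0.840923027609445	0.356950647590943	0.4067366430758
CP5	-0.840923027609445	-0.356950647590944	0.4067366430758
CP6	0.840923027609445	-0.356950647590943	0.4067366430758
Fp1	-0.308828749571334	0.950477158362114	-0.0348994967025007
Fp2	0.308828749571334	0.950477158362114	-0.0348994967025007
F7	-0.838159672495552	0.54430725563055	-0.0348994967025007
F8	0.838159672495552	0.54430725563055	-0.0348994967025007
T7	-0.999390827019096	1.22390077740616e-16	-0.0348994967025007
T8	0.999390827019096	0	-0.0348994967025007
P7	-0.838159672495552	-0.54430725563055	-0.0348994967025007
P8	0.838159672495552	-0.54430725563055	-0.0348994967025007
O1	-0.308828749571334	-0.950477158362114	-0.0348994967025007
O2	0.308828749571334	-0.950477158362114	-0.0348994967025007
Oz	6.11950388703081e-17	-0.999390827019096	-0.0348994967025007
PO3	-0.413383038747957	-0.886502787416264	0.207911690817759
PO4	0.413383038747957	-0.886502787416264	0.207911690817759
PO7	-0.587427189398202	-0.808524163080882	-0.0348994967025007
PO8	0.587427189398203	-0.808524163080882	-0.0348994967025007
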